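id,cas_rn,name,state,in_vivo_category,tg492_ps,pip1_prediction,recoverability,final_class
1,1760-24-3,(Ethylenediamine-propyl)-trimethoxysilane,liquid,CAT1,1,irritant,NT,strong
2,2365-48-2,Methylthioglycolate,liquid,CAT1,1,irritant,I,strong
3,818-61-1,Hydroxyethyl acrylate,liquid,CAT1,1,irritant,NT,strong
4,17831-71-9,Tetraethylene glycol diacrylate,liquid,CAT1,0,irritant,NT,strong
5,18472-51-0,"2,4,11,13-Tetraazatetradecane-diimidamide, N,N''-bis(4-chlorophenyl)-3,12-diimino-, di-D-gluconate (20%, aqueous)",liquid,CAT2A,1,irritant,NT,strong
6,96-48-0,gamma-Butyrolactone,liquid,CAT2A,1,irritant,R,moderate_or_mild
7,104-76-7,2-Ethyl-1-hexanol,liquid,CAT2A,0,irritant,NT,strong
8,67-64-1,Acetone,liquid,CAT2A,0,irritant,R,moderate_or_mild
9,67-63-0,Isopropyl alcohol,liquid,CAT2A,0,irritant,R,moderate_or_mild
10,105-34-0,Methyl cyanoacetate,liquid,CAT2A,0,non_irritant,NT,non_irritant
11,78-93-3,Methyl ethyl ketone (2-butanone),liquid,CAT2A,0,irritant,R,moderate_or_mild
12,111-27-3,n-Hexanol,liquid,CAT2A,0,irritant,R,moderate_or_mild
13,96-41-3,Cyclopentanol,liquid,CAT2A,0,irritant,R,moderate_or_mild
14,1569-01-3,Propylene glycol propyl ether,liquid,CAT2A,0,irritant,R,moderate_or_mild
15,9002-93-1,Triton X-100 (5%),liquid,CAT2A,0,irritant,R,moderate_or_mild
16,105-30-6,2-Methyl-1-pentanol,liquid,CAT2B,1,irritant,R,moderate_or_mild
17,134-62-3,Diethyl toluamide,liquid,CAT2B,1,irritant,R,moderate_or_mild
18,29911-27-1,1-(2-Propoxy-1-methylethoxy)-2-propanol,liquid,CAT2B,0,irritant,R,moderate_or_mild
19,542-76-7,3-Chloropropionitrile,liquid,CAT2B,0,non_irritant,NT,non_irritant
20,609-14-3,Ethyl-2-methylacetoacetate,liquid,CAT2B,0,irritant,R,moderate_or_mild
21,78-84-2,Isobutyraldehyde,liquid,CAT2A,0,irritant,NT,strong
22,542-08-5,Isopropyl acetoacetate,liquid,CAT2B,0,non_irritant,NT,non_irritant
23,123-72-8,n-Butanal,liquid,CAT2B,0,irritant,I,strong
24,342573-75-5,1-Ethyl-3-methylimidazolium ethylsulfate,liquid,NO_CAT,1,non_irritant,NT,non_irritant
25,2370-63-0,2-Ethoxyethyl methacrylate,liquid,NO_CAT,1,non_irritant,NT,non_irritant
26,13826-35-2,3-Phenoxybenzyl alcohol,liquid,NO_CAT,1,irritant,NT,strong
27,3446-89-7,4-(Methylthio)-benzaldehyde,liquid,NO_CAT,1,non_irritant,NT,non_irritant
28,629-19-6,Dipropyl disulfide,liquid,NO_CAT,1,non_irritant,NT,non_irritant
29,623-51-8,Ethyl thioglycolate,liquid,NO_CAT,1,irritant,I,strong
30,51-03-6,Piperonyl butoxide,liquid,NO_CAT,1,non_irritant,NT,non_irritant
31,61788-85-0,Polyethylene glycol (PEG-40) hydrogenated castor oil,liquid,NO_CAT,1,irritant,I,strong
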