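# eyeirr

Hazard identification for eyes without animals: `eyeirr` implements the
computational side of an in vitro eye irritation test on a reconstructed
human cornea-like epithelium (RhCE) tissue model. It is aimed at
toxicologists and assay developers who need to go from raw WST-8
plate-reader exports to UN GHS ocular-hazard predictions — and to the
validation statistics regulators ask for under OECD TG 492 / TG 492B.

## What it computes

**Viability.** Each well's dual-wavelength absorbance is blank-corrected,

    od = (A450 − A650) − mean[(A450 − A650)]_blank

and expressed relative to the day-1 untreated control (or, at recovery
timepoints, the same-day negative control):

    viability_i = 100 · od_i / mean(od_reference),

averaged over tissue replicates. Runs are gated by QC on the negative and
positive controls.

**Classification.** A threshold decision framework maps each chemical's
viability trajectory over the post-incubation period (PIP) to a GHS
category:

- mean day-1 viability **> 70 %** (the EC70 cut-off) → non-irritant, *No Cat.*;
- day-1 viability **≤ 5 %** → strong irritant, *Cat. 1* (fast-tracked, no
  recovery monitoring);
- otherwise the tissue is monitored at PIP days 7 and 14: viability
  **> 50 %** of the negative control at either day means the damage is
  reversible → moderate/mild irritant, *Cat. 2*; never exceeding 50 % by
  day 14 means irreversible → strong irritant, *Cat. 1*.

**Performance.** Predictions are scored against in vivo (Draize-test)
reference categories: the day-1 2×2 table with sensitivity, specificity
and accuracy checked against the TG 492 performance standard
(≥ 90 / ≥ 60 / ≥ 75 %), and the final 3×3 table with per-category
predictivity and balanced accuracy (trace/total) checked against the
TG 492B criteria (Cat. 1 ≥ 75 %, Cat. 2 ≥ 50 %, No Cat. ≥ 70 %).

The package ships the 31-chemical liquid validation panel
(`load_liquid_panel()`) and a synthetic plate-data generator
(`simulate_trajectories()`, `emit_plates()`) that emulates
category-dependent damage and recovery kinetics, so the entire pipeline
runs and is testable with no wet-lab data.

## Worked example

```r
library(eyeirr)
print(evaluate_reference_panel())
```

```
Reference panel evaluation (31 liquid chemicals)

Day-1 prediction (2x2):
              in vivo
prediction     Cat 1/2 No Cat
  irritant          20      3
  non_irritant       3      5
sensitivity 87.0% (20/23), specificity 62.5% (5/8), accuracy 80.6% (25/31)
TG492_PS criteria: NOT MET
  sensitivity >= 90%: 87.0% -> fail
  specificity >= 60%: 62.5% -> pass
  accuracy >= 75%: 80.6% -> pass

Final classification (3x3):
         in_vivo
predicted CAT1 CAT2 NO_CAT
   CAT1      4    4      3
   CAT2      0   12      0
   NO_CAT    0    3      5
predictivity: Cat 1 100.0% (4/4), Cat 2 63.2% (12/19), No Cat 62.5% (5/8)
balanced accuracy (trace/total): 67.7% (21/31)
TG492B criteria: NOT MET
  CAT1 >= 75%: 100.0% -> pass
  CAT2 >= 50%: 63.2% -> pass
  NO_CAT >= 70%: 62.5% -> fail

Strata: 7 fast-tracked strong (day-1 <= 5%), 16 monitored at days 7/14,
        12 moderate/mild, 8 non-irritant
```

Reading: of 23 in vivo irritants, 20 read ≤ 70 % viability on day 1
(sensitivity 87.0 %); all 4 Cat. 1 chemicals are recovered by the recovery
analysis (predictivity 100 %), while 3 of 8 No Cat. chemicals are
overestimated as strong irritants, which is why the No Cat. criterion
fails.

A full plate-level analysis of simulated data:

```r
spec <- simulation_spec(n_per_category = 10, noise_sd = 2, seed = 1)
sim <- simulate_trajectories(spec)
run <- emit_plates(sim$trajectories, spec)
write_plate_csv(run, "readings.csv", "layout.csv")
report <- run_pipeline("readings.csv", "layout.csv",
                       chemicals = data.frame(id = sim$truth$chemical_id,
                                              in_vivo_category = sim$truth$category))
print(report)
```

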