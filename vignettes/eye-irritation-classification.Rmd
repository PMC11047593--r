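---
title: "Classifying ocular hazard from RhCE viability trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ocular hazard from RhCE viability trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(eyeirr)
```

## The measurement model

A reconstructed human cornea-like epithelium (RhCE) tissue is exposed to a
liquid chemical for 5 minutes, rinsed, and returned to culture. Tissue
viability is then measured non-destructively with the WST-8 tetrazolium
assay: metabolically active cells reduce the dye to a soluble formazan, and
the supernatant's absorbance at 450 nm (with 650 nm as an optical
reference) is proportional to the amount of viable tissue. Because the
assay does not destroy the tissue, the *same* construct can be re-measured
over a post-incubation period (PIP) of days to weeks — this is what lets a
single-endpoint irritancy test become a recovery-kinetics test that can
separate reversible from irreversible damage.

The quantification chain is deliberately simple and fully determined by
the plate:

1. per-well signal `A450 − A650`;
2. blank correction by the mean signal of the WST-8-only blank wells of the
   same day (the number of blanks is a layout choice; the mean is used);
3. viability as a percentage of the mean blank-corrected od of the
   reference wells — the untreated control at day 1, the same-day negative
   control (3-methoxy-1,2-propanediol) at recovery days;
4. unweighted arithmetic mean over tissue replicates (at least two).

Two consequences worth noting. Viability is invariant to any common
rescaling of the absorbances of a day (reader gain, incubation time), and
the reference role's mean viability is exactly 100 by construction — both
are enforced as tests. Negative ods can occur by noise and are *retained*,
not clipped (clipping would bias mean viability upward); ods below −0.05
absorbance units are flagged as suspicious. Since every classification
rule below treats small viabilities identically (anything ≤ 5 % is the
same verdict), slight negativity is harmless downstream.

## The decision framework

Each chemical yields a trajectory `v(day)` of mean viabilities. The rules
fire in order on the day-1 value:

| rule | condition | verdict |
|------|-----------|---------|
| EC70 | `v(1) > 70` | non-irritant → No Cat. |
| fast-track | `v(1) ≤ 5` | strong irritant → Cat. 1 (no monitoring) |
| recovery | `5 < v(1) ≤ 70` and `v(7) > 50` or `v(14) > 50` | reversible → moderate/mild → Cat. 2 |
| no recovery | `5 < v(1) ≤ 70` and neither exceeds 50 | irreversible → strong → Cat. 1 |

Boundary semantics follow the verbatim inequalities of the protocol:
the EC70 boundary itself is an irritant (`≤ 70`), 5 % is inclusive for the
fast track, and recovery requires *strictly* more than 50 % of the
negative control. Where the protocol's tabular and prose statements of the
EC70 rule disagree on inclusivity, the strict reading (`> 70` for
non-irritant) is adopted: the irritant row is stated as `≤ 70`, and both
cannot contain the boundary.

Three further design choices were genuinely open:

- **Early stopping.** A chemical that has recovered at day 7 need not be
  measured at day 14; a chemical *not yet* recovered at day 7 without a
  day-14 measurement is an *incomplete trajectory* and raises an error
  rather than defaulting to either verdict.
- **Time-dependent recovery past EC70.** The framework admits an optional
  rule — off by default (`allow_late_noncat`) — that re-classes a
  monitored chemical as non-irritant when its trajectory increases
  strictly and ends above 70 %. No chemical in the packaged panel
  exhibits that outcome, which is why the default is off; the exact
  attachment point of this footnote rule in the framework is an
  interpretation, and keeping it behind a flag makes the interpretation
  inert unless requested.
- **PIP-21 and beyond.** Measurements after day 14 do not enter
  classification (later timepoints serve histology, and RhCE constructs
  degrade in extended culture); the classifier ignores them.

Severity maps one-to-one onto predicted GHS categories (strong → Cat. 1,
moderate/mild → Cat. 2, non-irritant → No Cat.). The framework does not
attempt the Cat. 2A/2B sub-split: recovery by day 7 versus day 14 showed
no usable correspondence to the sub-categories, so the prediction stops at
Cat. 2.

## Run QC

A run is interpretable only if its controls behave: the negative control
must read above the EC70 cut-off, the 10 % benzalkonium chloride positive
control at or below it. A third, optional check compares the untreated
control's raw od against a batch-specific nominal value ± 30 %; suitable
od ranges are a property of each tissue batch, so the nominal od is
supplied per run (`qc_config`) and the check is skipped when absent.
Classification refuses to run on a QC-failed run.

## Validation statistics

`evaluate_reference_panel()` scores the packaged 31-chemical liquid panel:

```{r panel}
rep <- evaluate_reference_panel()
rep$performance$binary
rep$performance$predictivity
```

Two conventions deserve explicit names. *Balanced accuracy* is reported
here as the overall fraction correct of the 3×3 table (trace/total,
21/31 = 67.7 %), matching how the benchmark quotes it; the mean of the
three per-category predictivities — the other common definition — is
exposed separately as `mean_predictivity` so the two are never conflated.
Reported percentages are rounded half-up to one decimal (87.0, 63.2,
81.3); criteria comparisons always use the exact fractions, and
zero-denominator metrics are flagged as undefined rather than coerced to
0 or 100.

## The synthetic-data generator

No raw absorbances or per-chemical viabilities are published for the
panel, so plate-level behaviour is validated on synthetic data built to
emulate the observed outcome strata. Trajectories follow an exponential
approach to a plateau,

$$v(t) = p - (p - v_1)\,e^{-k (t-1)},$$

the simplest kinetic shape consistent with the recovering and
non-recovering viability curves seen in practice (the protocol itself
prescribes no kinetic model). Default profiles per generating category:

- **No Cat.**: day-1 viability uniform on 80–95 %, no monitoring;
- **Cat. 2**: day-1 uniform on 25–55 %, reversible with plateau 90 % and
  k = 0.3 /day (recovery crosses 50 % before day 7);
- **Cat. 1**: day-1 uniform on 15–35 %, irreversible with plateau 35 %
  (never crosses 50 %).

Every default stratum keeps **≥ 10 percentage points of margin** from each
decision threshold (5/50/70), so noiseless classification is exact by
construction and misclassification under Gaussian noise of a few points
requires multi-sigma excursions; a separate `boundary_profiles()` preset
concentrates mass *on* the EC70 boundary for stress tests, where symmetric
noise must split predictions about 50/50. As in the real protocol, whether
a simulated chemical is monitored at days 7/14 is decided from its
*measured* (noisy) day-1 value, not its latent one.

Noise enters at two levels: additive Gaussian noise on viability
(`noise_sd`, percentage points — summarizing all biological
tissue-to-tissue variation) and optional multiplicative noise on emitted
od (`od_noise_cv` — plate-reader noise scales with signal). Plates are
emitted as `A650 = baseline` and
`A450 = A650 + blank od + (v/100)·dynamic range`, making the
emit → quantify pipeline exactly invertible at zero noise (verified to
10⁻⁹). Seeds are mandatory in `simulation_spec()`; there is no hidden
global RNG state.

What the simulation does *not* emulate: chemical-specific optical
interference with WST-8 (colored or reducing chemicals), within-plate
spatial effects, batch drift across runs, and tissue breakdown in
long-term culture. Passing parameter-recovery tests therefore demonstrates
the *software's* correctness under the stated noise model, not the
biological performance of the assay — the latter is what the packaged
panel statistics measure.

## Problem sizes used in tests

The parameter-recovery experiment in the test suite and acceptance script
uses 100 chemicals per category (n = 300) at `noise_sd = 2` with fixed
seeds — large enough that a >99 % accuracy assertion has negligible
sampling slack under the 10-point margins, and small enough to run in
seconds. The monotone noise-degradation property is checked on a coarse
noise grid (0, 4, 12, 30 points) at 40 chemicals per category, with a 5 %
sampling-slack allowance between adjacent levels.

## Known limitations

- The panel fixture stores categorical outcomes only; no per-chemical
  numeric viabilities exist to regress against.
- Solid chemicals are out of scope: the protocol modelled here is the
  5-minute liquid protocol, and physical state is known to change the
  test's predictive capacity.
- QC od bands are batch properties and must be configured per laboratory;
  the package cannot supply universal defaults.
- `balanced_accuracy` follows the trace/total convention of the benchmark;
  users wanting mean-of-recalls should read `mean_predictivity`.
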