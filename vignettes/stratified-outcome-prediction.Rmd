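---
title: "Stratified prediction of post-stroke upper-limb outcomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified prediction of post-stroke upper-limb outcomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokestrat)
```

## The question and the model

Upper-limb motor outcome three months after stroke (UE-FMA score at 3 M,
0–66) is predicted from baseline impairment (UE-FMA at 2 W) and from
measures of lesion-induced structural damage, using multiple linear
regression without regularisation. The package's central question is
whether fitting separate models to clinically stratified subgroups —
rather than one model to the whole cohort — reduces prediction error,
measured as mean squared error (MSE) under leave-one-out cross-validation
(LOOCV) and summarised as a size-weighted overall MSE relative to the
whole-group model.

Thirteen models are fitted per group: baseline alone (`B`), each of six
damage measures alone (`PF`, `CF`, `LL`, `DL`, `LV`, `DV`), and baseline
plus each measure (`B + ·`). Damage measures never co-occur in one model
because they are strongly mutually correlated (the package's
`partial_correlation_matrix` quantifies this multicollinearity after
removing age, sex and dominance). Age, sex and hemispheric motor dominance
enter every model as confounding covariates. Within each group, each
combination model is compared against `B` by a likelihood-ratio χ² test
(`n log(RSS_reduced/RSS_extended)`), with Benjamini–Hochberg adjustment
across the six comparisons of that group; the adjustment family is
per-group because the six tests share a response and a baseline model.

## Damage measures

Each measure applies a *damage map* (FA map, binary lesion, or
disconnectome) to an *ROI* (patient CST, control CST, or whole brain):

* **CST territories** retain streamlines passing through three waypoint
  regions — precentral gyrus, posterior limb of the internal capsule and
  pons analogues — in order-free fashion, excluding streamlines that cross
  the inter-hemispheric midline or enter an optional exclusion zone.
  Voxel-wise pass-through counts are normalised to their maximum; the
  control territory is the average of the per-control normalised maps.
* **Disconnectomes** select, per normative control, the streamlines
  intersecting any lesion voxel, normalise voxel counts to that control's
  maximum, and average over controls; values lie in [0, 1].
* **FA asymmetry** is (FA_contra − FA_ipsi)/(FA_contra + FA_ipsi) of
  per-hemisphere mean FA within the territory. The means are weighted by
  the territory's probability-like weights by default; whether the field's
  convention weights or binarises the territory is ambiguous, so
  `weighted = FALSE` switches to binarised-ROI means for sensitivity
  analyses.
* **Loads and volumes** are weighted overlap volumes
  Σ damage·roi · voxel-volume, reported in mm³ (the alternative, raw voxel
  counts, differs only by the constant voxel volume; mm³ is stated in all
  output headers).

Numerical conventions: voxel-centre continuous coordinates; the midline
sits at the midpoint of the left–right axis (an odd midline voxel row
belongs to neither hemisphere); a streamline visits a voxel if any point
of the polyline, resampled at a half-voxel arc-length step, rounds into
it — resolution-robust and deterministic.

## Stratification

Four strategies, thresholds taken verbatim from the clinical definitions
and both inclusive:

* initial impairment: severe iff FMA_2W ≤ 20;
* lesion location: cortical iff the lesion involves cortical areas (an
  input flag, mirroring radiological classification);
* neurophysiological: MEP-negative iff no motor evoked potential;
  subjects without MEP measurement are excluded from this strategy only;
* proportional recovery: non-fitted iff the model residual
  (66 − FMA_2W)·0.7 − (FMA_3M − FMA_2W) is ≥ 20.

## Model fitting and selection

OLS via QR decomposition; singular designs raise an error rather than
being silently pseudo-inverted, because silent rank reduction would
corrupt the parameter count `k` and hence AICc. LOOCV uses the exact
hat-matrix identity `e_i/(1 − h_ii)`, which the tests verify against
explicit per-fold refits to 1e-8; a leverage of 1 raises a named fold
error. AICc uses the Gaussian-likelihood form with all constants retained,

`n log(RSS/n) + n log(2π) + n + 2k + 2k(k+1)/(n − k − 1)`,

with `k` counting the intercept and the error variance. Any
shared-constant convention preserves the model ranking, which is all the
analysis uses; absolute AICc values are convention-dependent and not
comparable across software.

Per stratum, the best model is the argmin of LOOCV MSE (generalisation)
and, independently, of in-sample MSE; ties break by fewer parameters, then
label order. Strata smaller than `k + 3` for a model, or degenerate for it
(e.g. two binary covariates differing in a single subject, which gives
that subject leverage 1), yield an explicitly skipped record instead of an
error; a stratum in which no model can be fitted propagates as an `NA`
aggregate with a warning. The stratified summary weights each stratum's
best MSE by its size, Σ n_g·MSE_g/Σ n_g, and reports it as a percentage of
the whole-group best model (100%), rounded to one decimal. For the MEP
strategy the default denominator is the measured subjects only
(`mep_denominator = "measured"`); `"whole"` instead counts unmeasured
subjects under the whole-group model. Both are provided because the
aggregation rule for partially measured strategies is genuinely ambiguous;
neither is canonical.

R² comparisons between combination models use a subject-resampling
bootstrap of the R² difference (default 1000 replicates, percentile
interval), since no standard closed-form test applies to non-nested
models sharing a response.

## The synthetic cohort generator

`generate_cohort` produces the joint structure the analysis assumes, on a
geometric phantom: a 3D grid (default 24³ voxels of 2 mm) whose first axis
is left–right, with a vertical CST-analogue corridor per hemisphere
passing through the three waypoint boxes, a cortical shell at the top of
the grid, ellipsoidal lesions confined to one hemisphere (with a second
lobe reaching the shell when the cortical flag is set), FA maps elevated
along the corridors and depressed inside lesions and along the damaged
corridor, and streamline bundles (plus midline-crossing background fibres)
for patients and controls.

The behavioural model, per subject:

* baseline score: `round(a + z)` clipped to the observed 4–63 range, where
  `z` mixes the negated standardised CST-corridor overlap with independent
  noise in ratio `damage_coupling : 1`, scaled to the observed baseline
  dispersion (sd 18.2); the intercept `a` is placed between order
  statistics of `z` so that the configured fraction (default 33/60) scores
  ≤ 20. The joint distribution of lesion size and initial severity is not
  identifiable from published summaries, so the coupling is a stand-in
  exposed as a config knob.
* outcome: fitted subjects receive the proportional-recovery prediction
  plus Gaussian noise (`recovery_noise_sd`, default 7 points — the value
  implied by a fitted-subgroup cross-validated MSE near 48) rounded and
  clipped to 4–66; non-fitted subjects receive a deficit
  `20 + (0.7(66 − FMA_2W) − 20)·clamp(overlap + noise)` below the
  prediction, re-checked against the residual ≥ 20 criterion with
  resampling (deterministic fallback `floor(pred − 20)`).
* membership: the probability of being non-fitted (and of being
  MEP-negative, among the measured) is logistic in the product of
  normalised CST overlap and a smooth severity weight
  `plogis((20.5 − FMA_2W)/4)`, with the intercept calibrated so the mean
  matches the configured fraction. The severity gate encodes the
  motor-reserve argument: recovery failure requires both substantial CST
  damage and severe initial impairment, which is also what makes damage
  measures informative *within* the severe subgroup while baseline alone
  suffices among the non-severe — the interaction a pooled linear model
  cannot express.

Defaults were calibrated once against the published summary profile (the
per-stratum best-model MSEs, whole-group R², and score dispersions):
`damage_coupling = 0.8`, `membership_slope = 4`, `deficit_noise_sd = 0.4`.
These reproduce the character of the observed table — whole-group CV MSE
above 120, a noisy severe stratum near 140, a cleaner non-severe stratum
near 100, fitted near 48 — and the size-weighted severity-stratified error
below the whole-group error in most replicates; the acceptance script
recomputes that fraction on every run. Demographics: age uniform on
28–80, sex balanced, dominant-side lesions at 27/60, scores integer
(the UE-FMA is a sum of 0/1/2 items).

What the generator does **not** emulate: real brain anatomy or
registration, diffusion-tensor estimation, realistic tractography
(bundles are jittered polylines through boxes), partial-volume effects,
measurement error in the UE-FMA itself, and cohort-level confounding
between demographics and lesion characteristics. Passing tests therefore
show that the pipeline's operations are correct and that its conclusions
hold under the stated generative assumptions — not that those assumptions
describe any particular clinical population.

## Problem sizes and determinism

Every stochastic stage derives from a single integer seed
(`synthetic_config(seed = )`; `run_pipeline` is byte-identical across
reruns of one seed). The test-suite and acceptance-script simulations use:
100 random problems for the LOOCV identity (n ≤ 60, k ≤ 6, 1e-8); a
500-subject cohort at reduced grid resolution (12³) for coefficient
recovery (200 replicates, 3-standard-error coverage pooled over
coefficients) and likelihood-ratio null calibration (1000 replicates,
Kolmogorov–Smirnov uniformity); and 50 replicate 60-patient cohorts (10
controls) for the end-to-end stratification comparison. These sizes keep
the full suite under a few minutes while leaving the binomial noise of
each checked fraction well inside its test margin.

## Known limitations

* The published per-model statistics of the motivating cohort depend on
  unreleased individual data; only the aggregation arithmetic of its
  summary table is exactly reproducible, and the package asserts exactly
  that (plus property-based checks of every operation).
* The MEP-strategy overall MSEs of that table are not derivable from its
  printed stratum cells under either aggregation mode implemented here;
  both modes are provided and documented, neither asserted as correct.
* LOOCV-based best-model selection over 13 models per stratum is noisy at
  n ≈ 30; the reported per-stratum minima are optimistically biased, as
  they are in the original analysis design.
* FA asymmetry is undefined when a territory is empty in either
  hemisphere; the generator guarantees bilateral bundles, but real data
  may not.
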