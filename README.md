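# strokestrat

Stratified prediction of upper-limb motor outcomes after stroke.

After a stroke, recovery of upper-limb function over the first three months
is remarkably lawful for most patients — the *proportional recovery rule*
predicts a gain of about 0.7 × (66 − baseline score) on the upper-extremity
Fugl-Meyer assessment (UE-FMA, 0–66) — but a sizeable minority recover far
less, and who they are is tied to structural damage of the corticospinal
tract (CST). `strokestrat` implements, as a tested R pipeline, the analysis
that asks: **does splitting a cohort into clinically meaningful subgroups
before fitting predictive models reduce prediction error?**

It is aimed at researchers in stroke rehabilitation and lesion–outcome
modelling who want a reproducible, simulation-backed implementation of:

1. **Six structural damage measures** (damage map × region of interest):

   | Damage map | ROI | Measure |
   |---|---|---|
   | FA | patient CST | patient CST FA asymmetry |
   | FA | control CST | control CST FA asymmetry |
   | lesion | control CST | CST lesion load |
   | disconnectome | control CST | CST disconnectome load |
   | lesion | whole brain | lesion volume |
   | disconnectome | whole brain | disconnectome volume |

   FA asymmetry is (FA_contra − FA_ipsi)/(FA_contra + FA_ipsi) of
   territory-weighted hemispheric means; loads and volumes are weighted
   overlap volumes Σ damage·roi·voxel-volume in mm³. CST territories are
   streamline pass-through counts (precentral → PLIC → pons waypoints,
   midline-crossers excluded) normalised to the maximum count;
   disconnectomes are normative-control streamlines passing through the
   lesion, normalised per control and averaged.

2. **Four stratifications**: initial impairment (severe: UE-FMA at 2 weeks
   ≤ 20), lesion location (cortical involvement), neurophysiological status
   (MEP-negative/-positive, where measured) and the proportional recovery
   rule (non-fitted: model residual (66 − FMA_2w)·0.7 − (FMA_3m − FMA_2w)
   ≥ 20). Both thresholds are inclusive.

3. **A 13-model linear family** (baseline alone; each damage measure alone;
   baseline + each measure; age, sex and hemispheric motor dominance as
   covariates in every model), fitted by OLS and compared by in-sample MSE,
   leave-one-out cross-validated MSE (exact hat-matrix identity), R², AICc
   and likelihood-ratio χ² tests with Benjamini–Hochberg correction.

4. **Size-weighted aggregation**: per-stratum best models (smallest LOOCV
   MSE) are combined as Σ n_g·MSE_g / Σ n_g and expressed as a percentage
   of the whole-group best model's MSE.

Because individual patient data are not redistributable, the package ships
a **synthetic cohort generator** (`generate_cohort`) producing behavioural
tables, ellipsoidal lesion phantoms, FA maps and toy streamline bundles
with the dependence structure the analysis assumes; every stage of the
pipeline is exercised end-to-end on it.

## Worked example

```r
library(strokestrat)

cfg <- synthetic_config(seed = 11)   # 60 patients, 77 controls
res <- run_pipeline(cfg)

subset(res$aggregates, select = c(strategy, overall_gen, pct_gen))
```

```
               strategy overall_gen pct_gen
1                 whole   121.56840   100.0
2    initial_impairment   107.95340    88.8
3       lesion_location   150.10238   123.5
4    neurophysiological   125.51087   103.2
5 proportional_recovery    42.32498    34.8
```

Reading: the whole-group best model cross-validates at MSE ≈ 122 (UE-FMA
points²). Fitting separate models per severity subgroup and weighting by
subgroup size gives 88.8% of that error — stratification by initial
impairment helps, while (on this replicate) lesion-location and MEP
stratification do not. Proportional-recovery stratification (34.8%) is a
reference rather than a practical strategy, since its labels use the
outcome itself. Per-stratum
best models, the full per-model statistics (R², AICc, LR tests) and the
measure table are in `res$table3`, `res$model_table` and `res$measures`;
`run_pipeline(cfg, out_dir = "out")` writes everything as delimited text
plus a JSON summary.

Lower-level entry points: `build_cst_territory`, `build_disconnectome`,
`compute_all_measures`, `partial_correlation_matrix`, `assign_strata`,
`fit_stratum_models`, `select_best`, `build_table3`.

## Limitations

Phantoms are geometric stand-ins: no real anatomy, registration,
diffusion-tensor estimation or tractography. See the methods vignette
(`vignettes/stratified-outcome-prediction.Rmd`) for the generative model,
parameter choices and calibration details.
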