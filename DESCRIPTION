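Package: strokestrat
Title: Stratified Prediction of Post-Stroke Upper-Limb Motor Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for predicting upper-limb motor outcomes after stroke
    from baseline impairment and lesion-induced brain structural damage.
    Computes six damage measures (corticospinal-tract FA asymmetries,
    lesion and disconnectome loads and volumes) from lesion masks, FA maps
    and normative streamline sets; stratifies cohorts by initial severity,
    lesion location, motor-evoked-potential status and the proportional
    recovery rule; fits and compares a family of thirteen linear predictive
    models per stratum via leave-one-out cross-validation, AICc and
    likelihood-ratio tests; and aggregates stratified errors into
    size-weighted overall errors. Includes a synthetic-cohort generator
    (behavioural table, volumetric phantoms, toy streamline bundles) so the
    whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
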