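Package: aphasiatwin
Title: Digital-Twin Modelling of Naming Recovery in Post-Stroke Aphasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital-twin analysis of anomia treatment outcomes in
    chronic post-stroke aphasia. Generates seeded synthetic cohorts whose
    demographic, health-factor, lesion-load, fractional-anisotropy and
    connectivity features follow configurable marginal distributions, together
    with longitudinal Philadelphia Naming Test trajectories driven by a known
    ground-truth linear process. Provides a fit-once/transform-many
    preprocessing pipeline (mean imputation, percentile winsorization,
    log1p of skewed predictors, standardization, one-hot encoding), an
    L2-regularized linear model trained by streaming Adam updates with
    prequential (predict-then-update) evaluation, counterfactual what-if
    simulation of modifiable health factors (diabetes, hypertension, BMI)
    under a frozen model, and variance-of-treatment-gain accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
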