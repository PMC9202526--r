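Package: cvdrisk
Title: Ten-Year Cardiovascular Risk Prediction with Regional Recalibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex-specific 10-year risk prediction for ischemic heart disease,
    ischemic stroke, and hemorrhagic stroke in Chinese adults, using seven
    predictors available in routine primary-care records (age, systolic and
    diastolic blood pressure, blood-pressure-lowering treatment, current daily
    smoking, self-reported diabetes, and waist circumference). The three
    cause-specific Cox submodels are combined into a total cardiovascular
    disease risk via conditional probability. The package ships the published
    coefficient sets, re-derives them from cohort data with a region-stratified
    Cox fitter (Efron ties, Breslow baseline survival pooled across regions),
    recalibrates baseline survival to a target region either from
    cross-sectional summaries (practical) or from observed 10-year risks
    (ideal), and evaluates discrimination (Harrell C with internal-external
    cross-validation), calibration (Nam-D'Agostino test, decile calibration
    tables), and incremental value (relative integrated discrimination
    improvement). A synthetic multi-region cohort generator with cause-specific
    exponential hazards makes the whole pipeline testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
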