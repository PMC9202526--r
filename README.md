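# cvdrisk

Ten-year cardiovascular risk prediction for Chinese adults, with
regional recalibration.

`cvdrisk` implements a family of sex-specific risk models that predict
the 10-year risk of ischemic heart disease (IHD), ischemic stroke (IS),
and hemorrhagic stroke (HS) — and their combination into total CVD risk
— from seven predictors available in China's routine resident health
records: age, systolic and diastolic blood pressure, use of
blood-pressure-lowering treatment, current daily smoking, self-reported
diabetes, and waist circumference. No blood lipids are required, which
is what makes the models deployable through primary-care records, and
hemorrhagic stroke is modelled separately because its burden in China
is far higher than in the Western populations most risk scores were
built on.

The package is aimed at biostatisticians and epidemiologists who want
to (a) compute risks from the published coefficient sets, (b) re-derive
the models on their own cohort data, (c) recalibrate the models to a
target region's disease rates, or (d) evaluate discrimination and
calibration the way the original development did.

## The model

Each cause-specific submodel is a Cox model on centered predictors in
model units (age per 5 years from 55; SBP/DBP per 10 mm Hg from
120/80; waist per 10 cm from 80; binaries 0/1), with age-by-predictor
interaction terms:

    LP_k = Σ_p β_kp u_p + Σ_{p≠age} γ_kp u_age u_p
    Risk_k = 1 − S0_k(10)^exp(LP_k),   k ∈ {IHD, IS, HS}
    Risk_CVD = 1 − (1−Risk_IHD)(1−Risk_IS)(1−Risk_HS)

The 10-year baseline survivals S0_k(10) are pooled over the ten study
regions of the derivation cohort, weighted by events within 10 years.
Recalibration to a new region replaces S0_k(10) only — practically,
from age-group mean covariates and annual incidences
(s0^c with c the weighted observed/predicted cumulative-hazard ratio),
or ideally, by matching mean predicted risk to the observed 10-year
Kaplan-Meier risk. Betas are never touched.

Around the model sit a region-stratified Cox fitter (Efron ties,
Newton-Raphson, Breslow baseline survival), leave-one-region-out
internal-external cross-validation with pooled Harrell C, a
Nam-D'Agostino calibration test with decile calibration tables, a
relative integrated-discrimination-improvement (IDI) statistic, and a
synthetic multi-region cohort generator so that every pipeline stage is
testable without restricted data. See the methods vignette
(`vignettes/risk-model-methods.Rmd`) for the modelling decisions and
their rationale.

## Worked example

```r
library(cvdrisk)

fam <- cvd_model("female")          # packaged published coefficients
profiles <- tibble::tibble(
  sex = "female", age = c(45, 62), sbp = c(118, 152), dbp = c(76, 88),
  bp_treatment = c(0, 1), daily_smoker = c(0, 0), diabetes = c(0, 1),
  waist = c(74, 88))
predict_cvd_risk(profiles, fam)[, c("age", "sbp", "risk_ihd", "risk_is",
                                    "risk_hs", "risk_cvd")]
#>   age sbp risk_ihd risk_is risk_hs risk_cvd
#> 1  45 118   0.0449  0.0374  0.0053   0.0856
#> 2  62 152   0.3450  0.3924  0.0832   0.6352
```

The 45-year-old with unremarkable blood pressure and waist has a 10-year
total CVD risk of 8.6%, dominated by IHD; the 62-year-old treated
hypertensive woman with diabetes reaches 63.5%, with ischemic stroke the
largest contributor. At the reference profile (age 55, SBP 120, DBP 80,
waist 80, no binary risk factors) every linear predictor is zero, so
each submodel returns exactly one minus its baseline survival — e.g.
`predict_submodel_risk(reference_profile("female"), fam$submodels$IHD)`
is 0.100 because the women's IHD baseline survival is 0.900.

A full synthetic study — simulate a 10-region cohort from the packaged
coefficients, refit the three submodels, recalibrate per region both
ways, and evaluate total-CVD discrimination and calibration — is one
call:

```r
pl <- run_pipeline(sim_config(n_per_region = 4000, n_regions = 5,
                              seed = 29, sex = "female"))
pl
#> <cvd_pipeline> female, n = 20000, 5 regions
#>   original  Harrell C 0.742, Nam-D'Agostino chi2 231.7
#>   practical Harrell C 0.754, Nam-D'Agostino chi2 17.6
#>   ideal     Harrell C 0.754, Nam-D'Agostino chi2 64.3
```

Regional recalibration improves pooled discrimination (the regions'
absolute risks differ, and recalibration restores the between-region
risk ordering) and sharply improves calibration.

There is also a thin command-line wrapper over the same functions
(`inst/cli/cvdrisk.R`) with subcommands `simulate`, `fit`, `predict`,
`recalibrate`, `evaluate`, and `pipeline`.

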