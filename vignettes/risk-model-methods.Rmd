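---
title: "Methods: the 10-year CVD risk models, their derivation, recalibration, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 10-year CVD risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The risk model

`cvdrisk` implements a family of sex-specific 10-year risk models for
three cardiovascular outcomes in Chinese adults aged 30-79: ischemic
heart disease (IHD), ischemic stroke (IS), and hemorrhagic stroke (HS).
The models were developed for settings where blood lipids are not
routinely available: the seven predictors — age, systolic and diastolic
blood pressure (SBP, DBP), use of blood-pressure-lowering treatment,
current daily smoking, self-reported diabetes, and waist circumference
(WC) — are all recorded in China's resident health records. Modelling
the three outcomes separately matters in this population because the
burden of hemorrhagic stroke is far higher than in Western populations
and the regional mix of the three outcomes varies strongly, so a single
composite model would entangle outcome-specific associations with the
regional case mix.

Each submodel is a Cox proportional-hazards model. Continuous predictors
enter linearly, centered and scaled to model units:

* age: per 5 years, centered at 55;
* SBP: per 10 mm Hg, centered at 120; DBP: per 10 mm Hg, centered at 80;
* WC: per 10 cm, centered at 80;
* binary predictors: 0/1, centered at 0 (absent).

Writing $u_p$ for predictor $p$ in these units, the linear predictor of
one submodel is

$$ LP = \sum_p \beta_p u_p \;+\; \sum_{p \neq \mathrm{age}} \gamma_p\, u_{\mathrm{age}} u_p , $$

where $\beta_p$ is the main-effect log-hazard-ratio and $\gamma_p$ the
age-interaction log-hazard-ratio. A deliberate documentation point: the
interaction coefficients are read as *per 5 years of age* — the
published tables print the interaction hazard ratios without a unit
annotation, and $u_{\mathrm{age}} = (\mathrm{age}-55)/5$ is the coding
under which they reproduce the printed values. Because all terms are
centered, $LP = 0$ at the reference individual (age 55, SBP 120, DBP 80,
WC 80, no treatment, non-smoker, no diabetes).

Absolute risk comes from the 10-year baseline survival $S_0(10)$, the
survival probability of the reference individual:

$$ \mathrm{Risk}_k = 1 - S_{0k}(10)^{\exp(LP_k)}, \qquad k \in \{\mathrm{IHD}, \mathrm{IS}, \mathrm{HS}\}. $$

Total CVD risk combines the three cause-specific risks by conditional
probability, assuming independence of the three processes:

$$ \mathrm{Risk}_{CVD} = 1 - (1-\mathrm{Risk}_{IHD})(1-\mathrm{Risk}_{IS})(1-\mathrm{Risk}_{HS}). $$

This identity holds in the package to machine precision by
construction, and implies
$\max_k \mathrm{Risk}_k \le \mathrm{Risk}_{CVD} \le \sum_k \mathrm{Risk}_k$.

### Packaged coefficients and their precision

The packaged JSON model files store, per predictor, the published hazard
ratio (for human audit) and the log-hazard-ratio used in computation.
The published tables print hazard ratios to two decimals and the exact
regression coefficients live in an inaccessible supplement, so the
packaged log-hazard-ratios are logs of the two-decimal values. All
parameter-recovery tests therefore use tolerances rather than equality;
`exp(beta)` agrees with each printed hazard ratio to well within 0.005.
Because decimal JSON loses the final bit of a double, the files also
carry exact hexadecimal float representations, which the reader
prefers; serializing and re-reading a model family reproduces
predictions bit for bit. The risk horizon is fixed at 10 years: only
$S_0(10)$ is published, so no other horizon is exposed.

## Derivation machinery

`fit_stratified_cox()` re-derives a submodel from individual-level
cohort data. Design choices, each of which was genuinely open:

* **Stratification.** The partial likelihood is stratified by region:
  each region keeps its own baseline hazard, and the log partial
  likelihood is the sum of per-region contributions. With a single
  region the fit reduces exactly to an unstratified Cox model (tested).
* **Ties.** Efron's approximation. Simulated event times are continuous,
  so ties are rare, but coarsened or rounded data produce them; Efron is
  the more accurate of the two standard choices and matches the default
  of mainstream survival software, which the test suite uses as an
  independent cross-check.
* **Optimizer.** Newton-Raphson with step-halving. Convergence requires
  both a small score (max |gradient| < 1e-7) and a small relative
  log-likelihood change (< 1e-9), with at most 100 iterations.
  Step-halving tolerates rounding-level likelihood decreases (relative
  1e-12) so the final Newton step is not halved away at the optimum.
  Coefficients exceeding 30 in absolute value abort with a
  complete-separation diagnosis. Covariates with no within-stratum
  variation carry no information in a stratified partial likelihood;
  they are frozen at 0 and reported with infinite variance rather than
  passed to the optimizer.
* **Censoring convention.** Hazards are cause-specific: a subject whose
  first event is a different CVD type or a death is censored at that
  time for the target outcome, so each subject contributes an event to
  at most one submodel. Unspecified-stroke events are events for
  total-CVD evaluation but belong to no submodel, since no submodel
  covers them.
* **Baseline survival.** Per region, the Breslow cumulative baseline
  hazard at 10 years evaluated at the centered covariate origin gives
  $S_{0r}(10) = \exp(-H_{0r}(10))$; a region with no events by 10 years
  reports 1 with a warning. The pooled $S_0(10)$ is the mean of the
  regional values weighted by the number of target-outcome events
  occurring by year 10.
* **Internal-external cross-validation.** Each region is left out in
  turn, the model is refit on the rest, and Harrell C is computed in the
  held-out region. The per-region concordances are pooled by
  inverse-variance fixed-effect weighting on the C scale — the published
  description says only "pooling", so the weighting scheme is this
  package's choice, pinned and tested; regions with too few comparable
  pairs are excluded with a warning.

## Recalibration

Both recalibration methods replace only the regional baseline survival;
regression coefficients are never re-estimated.

**Practical recalibration** uses cross-sectional summaries alone: per
5-year age band $g$, the band's mean-covariate profile gives a predicted
10-year cumulative hazard $\hat H_g = \exp(LP_g)\,(-\ln S_0(10))$, and
the band's annual incidence $\lambda_g$ gives an observed cumulative
hazard $H_g = 10\lambda_g$. The correction factor is the
population-share-weighted ratio
$c = \sum_g w_g H_g \big/ \sum_g w_g \hat H_g$, and the regional
baseline survival becomes $S_0(10)^c$ — a proportional correction on the
cumulative-hazard scale, the mechanism of the WHO risk-chart
recalibration family. The exact matching scale of the original
procedure is not published, so this form is declared, isolated behind
one function, and anchored by a self-consistency contract: a table whose
incidences are exactly what the model predicts yields $c = 1$ (to 1e-6),
and doubling every incidence yields $c = 2$. Band means of binary
predictors are prevalences and enter the linear predictor as such. Two
readings of "annual incidence" are supported: events per person-year
(default, $H_g = 10\lambda_g$) and annual risk
($H_g = -10\ln(1-\lambda_g)$).

**Ideal recalibration** assumes the observed 10-year risk of the region
is known: the Kaplan-Meier risk at 10 years (competing events censored,
consistent with the derivation convention). The new baseline survival
solves $\operatorname{mean}_i\!\big[1 - s^{\exp(LP_i)}\big] =
\mathrm{risk}_{obs}$, a strictly monotone equation solved by 1-D root
finding on (0, 1); the root is verified against a bisection oracle to
1e-8, and the residual mean-risk gap is required to vanish to 1e-10. A
region with observed risk 0 gets baseline survival 1 with a warning.

Within a region, each submodel's recalibrated risk is a strictly
monotone transform of its original risk, so within-region concordance
per outcome is bit-identical before and after recalibration (tested as
such). The *combined* CVD risk is not a monotone transform — the three
submodels receive different correction factors, which can reorder
subjects — so the combined within-region concordance may move
marginally; across a multi-region cohort, recalibration reorders
subjects *between* regions toward the regional absolute risks, which is
why pooled concordance improves: original ≤ practical ≤ ideal.

## Evaluation statistics

* **Harrell C** is computed by `survival::concordance` behind the
  package surface (reversed so larger risk means earlier event), with
  risk ties counting 0.5 and a 95% CI from the asymptotic standard
  error. The test suite verifies it against explicit pair enumeration.
* **Nam-D'Agostino test.** Several variance forms of this statistic
  circulate; the package pins
  $\chi^2 = \sum_g n_g (KM_g - \bar p_g)^2 / (\bar p_g (1-\bar p_g))$
  over deciles of predicted risk on $g-1$ degrees of freedom, with
  $KM_g$ the Kaplan-Meier observed 10-year risk and $\bar p_g$ the mean
  predicted risk of decile $g$. This form is oracle-tested, not claimed
  identical to any one published variant. Decile boundaries are
  quantiles of predicted risk with ties assigned to the lower group;
  empty or degenerate deciles are errors.
* **Relative IDI.** The discrimination slope of a model is the mean
  predicted risk in subjects with an event by year 10 minus the mean in
  subjects event-free at year 10; IDI is the difference of slopes
  between two models and relative IDI expresses it as a percentage of
  the base slope. Subjects censored before the horizon without an event
  belong to neither group and are excluded — a simple convention chosen
  here because the source description is silent; at the <1%
  loss-to-follow-up levels the models target, the choice is immaterial.

## The synthetic cohort generator

`simulate_cohort()` exists so that derivation, recalibration, and
evaluation are exercisable without access to the restricted source
cohort. It emulates the *structure* of the study: per-sex covariate
distributions centered on the published baseline summaries (daily
smoking 2.0% of women and 57.1% of men; treatment 11.8%/10.2%; diabetes
2.9%/2.5%; SBP medians 126/129.5 and DBP 76/78.5 mm Hg; WC medians
78.2/81.3 cm), age uniform on 30-79, three cause-specific exponential
event processes with hazards
$\lambda_k = \lambda_{0k,r}\exp(LP_k)$, administrative censoring uniform
on 10-13 years, and 0.8% random loss to follow-up. Declared generator
defaults not taken from any publication: SBP/DBP standard deviations
20/11 mm Hg with correlation 0.7 (WC standard deviations from the
printed interquartile ranges), a constant competing non-CVD death hazard
of 0.005 per person-year, and an unspecified-stroke hazard equal to 1.3%
of the combined stroke hazard (so unspecified strokes are a realistic
~1.3% of strokes, events for total CVD but for no submodel).

Outcome-level baseline hazards are
$\lambda_{0k} = -\ln S_{0k}(10)/10$, so a region with multiplier 1
reproduces the published baseline survivals exactly in expectation;
per-region multipliers span [0.5, 2] on a geometric grid, rotated across
outcomes so regions differ in their outcome mix — the regional
heterogeneity that makes recalibration consequential. Constant
(exponential) hazards are the deliberate default because they admit
closed-form checks (e.g., the competing-risk cumulative incidence
$\lambda_k/\Lambda\,(1-e^{-10\Lambda})$); a shared Weibull shape is
exposed for robustness experiments. Age is fixed at baseline — no aging
during follow-up — matching the baseline-covariate form of the models.

What the generator does *not* emulate: the real joint covariate
distribution (covariates are drawn independently apart from the SBP-DBP
correlation, and clamping to admissible ranges creates boundary atoms),
age-dependent background mortality, non-proportional hazards, regional
differences in covariate distributions, or the identities of actual
regions. Passing tests therefore demonstrate correctness of the
machinery under the model's own assumptions, not transportability to
real data.

## Problem sizes and reproducibility

Parameter-recovery runs use 200,000 subjects per sex (10 regions x
20,000) — at that size every main-effect hazard ratio is recovered
within three simulation standard errors of its generating value, and the
published headline effects (e.g., DBP 1.33 for men's HS; WC 1.16 for
women's IHD and 0.92 for women's HS) are reproduced to within about 1%.
Property tests use 4,000-20,000 subjects per scenario, sizes at which
the checked inequalities are comfortably outside Monte-Carlo noise. All
randomness flows from a single integer seed per configuration
(Mersenne-Twister with inversion sampling for normals), and the pipeline
report is byte-reproducible under a fixed seed.

## Known limitations

* The packaged coefficients inherit the two-decimal precision of the
  published hazard ratios; individual risks can differ by a fraction of
  a percent from values computed with the unpublished full-precision
  coefficients.
* The Nam-D'Agostino variance form is pinned, not matched to the
  original report; absolute chi-square values are comparable within this
  package, not across implementations.
* Proportional-hazards diagnostics are not automated; the fitted model
  object exposes enough (per-subject linear predictors via the design
  matrix, per-region baselines) to produce Schoenfeld-style plots with
  the survival package, but no verdict is enforced.
* The independence assumption behind the conditional-probability
  combination is taken from the source models; the generator's competing
  causes are conditionally independent given covariates, so the package
  cannot detect violations of that assumption in real data.
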