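# Independent oracles and fixture builders shared across the test files.
# Each oracle is a deliberately naive reimplementation (enumeration, grid
# search, closed form) that never touches the package's computational
# path.

# Stratified Cox partial log-likelihood for a single covariate, written
# directly from the definition (no ties expected in the fixtures).
oracle_partial_loglik <- function(b, x, time, status, strata) {
  ll <- 0
  for (s in unique(strata)) {
    ix <- which(strata == s)
    xs <- x[ix]; ts <- time[ix]; ev <- status[ix]
    for (i in which(ev == 1)) {
      risk <- which(ts >= ts[i])
      ll <- ll + b * xs[i] - log(sum(exp(b * xs[risk])))
    }
  }
  ll
}

# 1-D grid-search maximizer of the partial likelihood (step 1e-4).
oracle_grid_beta <- function(x, time, status, strata, lo = -3, hi = 3,
                             step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, oracle_partial_loglik, 0, x = x, time = time,
               status = status, strata = strata)
  grid[which.max(ll)]
}

# Harrell C by explicit pair enumeration: pair (i, j) is usable when the
# subject with the earlier time has an event; ties in risk count 0.5.
# Fixtures use distinct times so time-tie conventions never matter.
oracle_harrell_c <- function(risks, time, status) {
  n <- length(risks)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      early <- if (time[i] < time[j]) i else j
      late <- if (time[i] < time[j]) j else i
      if (status[early] != 1) next
      usable <- usable + 1
      conc <- conc + if (risks[early] > risks[late]) 1
        else if (risks[early] == risks[late]) 0.5 else 0
    }
  }
  list(c = conc / usable, n_pairs = usable)
}

# Product-limit (Kaplan-Meier) risk at a horizon, from the definition.
oracle_km_risk <- function(time, status, horizon) {
  surv <- 1
  for (t in sort(unique(time[status == 1 & time <= horizon]))) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    surv <- surv * (1 - d / at_risk)
  }
  1 - surv
}

# Bisection root of mean(1 - s^elp) = target on (0, 1).
oracle_bisect_s0 <- function(elp, target, tol = 1e-12) {
  lo <- 1e-12; hi <- 1 - 1e-12
  f <- function(s) mean(1 - s^elp) - target
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Random valid risk profiles, uniform over the admissible ranges.
random_profiles <- function(n, sex = "female", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sbp <- runif(n, 90, 220)
  tibble::tibble(
    sex = sex,
    age = runif(n, 30, 79),
    sbp = sbp,
    dbp = pmin(runif(n, 50, 120), sbp),
    bp_treatment = rbinom(n, 1, 0.3),
    daily_smoker = rbinom(n, 1, 0.3),
    diabetes = rbinom(n, 1, 0.2),
    waist = runif(n, 55, 130)
  )
}

# A model family with every hazard ratio 1 (no discrimination) and given
# baseline survivals, used to simulate covariate-independent event times.
make_null_family <- function(sex, s0 = c(IHD = 0.9, IS = 0.91, HS = 0.986)) {
  ones <- setNames(rep(1, 7), c("age", "sbp", "dbp", "bp_treatment",
                                "daily_smoker", "diabetes", "waist"))
  ones_int <- ones[setdiff(names(ones), "age")]
  model_family(
    coef_set("IHD", sex, ones, ones_int, s0[["IHD"]]),
    coef_set("IS", sex, ones, ones_int, s0[["IS"]]),
    coef_set("HS", sex, ones, ones_int, s0[["HS"]])
  )
}

# Hand-buildable cohort rows with neutral covariates; events/times are the
# interesting part of these fixtures.
toy_cohort <- function(time, event, region = "1", sex = "female",
                       age = 55, sbp = 120, dbp = 80, waist = 80,
                       bp_treatment = 0, daily_smoker = 0, diabetes = 0) {
  n <- length(time)
  tibble::tibble(
    id = paste0("T", seq_len(n)), region = rep_len(as.character(region), n),
    sex = rep_len(sex, n), age = rep_len(age, n), sbp = rep_len(sbp, n),
    dbp = rep_len(dbp, n), bp_treatment = rep_len(bp_treatment, n),
    daily_smoker = rep_len(daily_smoker, n),
    diabetes = rep_len(diabetes, n), waist = rep_len(waist, n),
    time = time, event = rep_len(event, length.out = n)
  )
}

# Table of printed hazard ratios used for transcription spot checks
# (verified against the published model tables).
printed_hr_spotchecks <- tibble::tribble(
  ~sex,     ~outcome, ~predictor,     ~type,   ~hr,
  "female", "IHD",    "age",          "main",  1.40,
  "female", "IHD",    "waist",        "main",  1.16,
  "female", "IS",     "diabetes",     "main",  1.82,
  "female", "IS",     "daily_smoker", "int",   0.93,
  "female", "HS",     "waist",        "main",  0.92,
  "female", "HS",     "dbp",          "main",  1.32,
  "male",   "IHD",    "diabetes",     "int",   0.91,
  "male",   "IS",     "age",          "main",  1.52,
  "male",   "HS",     "dbp",          "main",  1.33,
  "male",   "HS",     "daily_smoker", "int",   1.00
)
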