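# Build a recalibration table whose incidences are exactly what the model
# family itself predicts for the band profiles: the self-consistency
# anchor for practical recalibration.
self_consistent_table <- function(family, region = "1", scale = 1) {
  ages <- c(42, 57, 72)
  tbl <- tibble::tibble(
    region = region, sex = family$sex,
    age_group = c("40-44", "55-59", "70-74"),
    population_share = c(0.5, 0.3, 0.2),
    age = ages, sbp = c(118, 128, 142), dbp = c(76, 80, 84),
    bp_treatment = c(0.05, 0.12, 0.25), daily_smoker = c(0.02, 0.02, 0.02),
    diabetes = c(0.01, 0.03, 0.06), waist = c(76, 79, 83)
  )
  for (k in c("IHD", "IS", "HS")) {
    cs <- family$submodels[[k]]
    u <- cvdrisk:::model_units(tbl)
    beta <- setNames(cs$terms$beta_main, cs$terms$predictor)
    gamma <- setNames(cs$terms$beta_age_interaction, cs$terms$predictor)
    others <- setdiff(names(beta), "age")
    lp <- drop(u %*% beta) +
      drop((u[, others, drop = FALSE] * u[, "age"]) %*% gamma[others])
    tbl[[paste0("incidence_", tolower(k))]] <-
      scale * exp(lp) * (-log(cs$s0_10)) / 10
  }
  tbl
}

test_that("practical recalibration is the identity on self-consistent incidence", {
  fam <- cvd_model("female")
  tbl <- self_consistent_table(fam)
  fam2 <- practical_recalibrate(fam, tbl)
  expect_lt(max(abs(fam2$recalibration$factors$correction - 1)), 1e-6)
  expect_equal(fam2$s0_overrides$s0_10,
               vapply(fam2$s0_overrides$outcome,
                      function(k) fam$submodels[[k]]$s0_10, 0,
                      USE.NAMES = FALSE),
               tolerance = 1e-9)
  # betas are untouched by construction
  expect_identical(fam2$submodels, fam$submodels)
})

test_that("practical recalibration is linear in the observed hazard", {
  fam <- cvd_model("male")
  fam2 <- practical_recalibrate(fam, self_consistent_table(fam, scale = 2))
  expect_equal(fam2$recalibration$factors$correction, rep(2, 3),
               tolerance = 1e-9)
  for (k in c("IHD", "IS", "HS")) {
    got <- fam2$s0_overrides$s0_10[fam2$s0_overrides$outcome == k]
    expect_equal(got, fam$submodels[[k]]$s0_10^2, tolerance = 1e-9)
  }
})

test_that("practical correction equals the hand-computed weighted hazard ratio", {
  fam <- cvd_model("female")
  tbl <- self_consistent_table(fam)
  # overwrite incidences with arbitrary values and recompute c by hand
  tbl$incidence_ihd <- c(0.004, 0.009, 0.020)
  tbl$incidence_is <- c(0.003, 0.008, 0.025)
  tbl$incidence_hs <- c(0.0005, 0.001, 0.004)
  fam2 <- practical_recalibrate(fam, tbl)
  for (k in c("IHD", "IS", "HS")) {
    cs <- fam$submodels[[k]]
    u <- cvdrisk:::model_units(tbl)
    beta <- setNames(cs$terms$beta_main, cs$terms$predictor)
    gamma <- setNames(cs$terms$beta_age_interaction, cs$terms$predictor)
    others <- setdiff(names(beta), "age")
    lp <- drop(u %*% beta) +
      drop((u[, others, drop = FALSE] * u[, "age"]) %*% gamma[others])
    H_hat <- exp(lp) * (-log(cs$s0_10))
    H_obs <- 10 * tbl[[paste0("incidence_", tolower(k))]]
    c_hand <- sum(tbl$population_share * H_obs) /
      sum(tbl$population_share * H_hat)
    got <- fam2$recalibration$factors$correction[
      fam2$recalibration$factors$outcome == k]
    expect_equal(got, c_hand, tolerance = 1e-12)
  }
  # the annual-risk scale variant uses -10 log(1 - q)
  fam3 <- practical_recalibrate(fam, tbl, incidence_scale = "risk")
  k <- "IHD"
  cs <- fam$submodels[[k]]
  u <- cvdrisk:::model_units(tbl)
  beta <- setNames(cs$terms$beta_main, cs$terms$predictor)
  gamma <- setNames(cs$terms$beta_age_interaction, cs$terms$predictor)
  others <- setdiff(names(beta), "age")
  lp <- drop(u %*% beta) +
    drop((u[, others, drop = FALSE] * u[, "age"]) %*% gamma[others])
  c_risk <- sum(tbl$population_share * (-10 * log(1 - tbl$incidence_ihd))) /
    sum(tbl$population_share * exp(lp) * (-log(cs$s0_10)))
  expect_equal(fam3$recalibration$factors$correction[
    fam3$recalibration$factors$outcome == k], c_risk, tolerance = 1e-12)
})

test_that("recalibration table validation enforces its invariants", {
  fam <- cvd_model("female")
  tbl <- self_consistent_table(fam)
  bad <- dplyr::mutate(tbl, population_share = c(0.5, 0.3, 0.1))
  expect_error(practical_recalibrate(fam, bad), "sum to 1")
  bad2 <- dplyr::mutate(tbl, incidence_is = c(-0.001, 0.002, 0.003))
  expect_error(practical_recalibrate(fam, bad2), "non-negative")
  expect_error(practical_recalibrate(fam, tbl, regions = "99"), "99")
  expect_error(practical_recalibrate(cvd_model("male"), tbl), "male")
})

test_that("ideal recalibration solves the mean-risk equation", {
  fam <- cvd_model("female")
  # closed form: all linear predictors 0 and observed risk 0.2 force
  # s0 = 0.8
  co_ref <- toy_cohort(time = c(rep(3, 2), rep(12, 8)),
                       event = c(rep("IHD", 2), rep("none", 8)))
  fam_ref <- suppressWarnings(ideal_recalibrate(fam, co_ref))
  got <- fam_ref$s0_overrides$s0_10[fam_ref$s0_overrides$outcome == "IHD"]
  expect_equal(got, 0.8, tolerance = 1e-9)

  # heterogeneous linear predictors: root agrees with a bisection oracle
  set.seed(3)
  n <- 400
  co <- dplyr::bind_cols(
    tibble::tibble(id = paste0("x", 1:n), region = "1"),
    random_profiles(n, "female"),
    tibble::tibble(time = runif(n, 0.5, 12),
                   event = sample(c("IHD", "IS", "HS", "none"), n, TRUE,
                                  prob = c(0.1, 0.08, 0.02, 0.8)))
  )
  fam2 <- ideal_recalibrate(fam, co)
  for (k in c("IHD", "IS", "HS")) {
    st <- cvdrisk:::outcome_status(co$event, k)
    target <- oracle_km_risk(co$time, st, 10)
    elp <- exp(linear_predictor(co, fam$submodels[[k]]))
    s_oracle <- oracle_bisect_s0(elp, target)
    got <- fam2$s0_overrides$s0_10[fam2$s0_overrides$outcome == k]
    expect_lt(abs(got - s_oracle), 1e-8)
    # the defining property: mean predicted risk equals observed risk
    expect_lt(abs(mean(1 - got^elp) - target), 1e-10)
  }

  # a region with no observed events pushes baseline survival to 1
  co0 <- toy_cohort(time = rep(12, 6), event = "none")
  w <- testthat::capture_warnings(fam0 <- ideal_recalibrate(fam, co0))
  expect_true(any(grepl("risk is 0", w)))
  expect_true(all(fam0$s0_overrides$s0_10 > 1 - 1e-9))
})

test_that("recalibration preserves within-region risk ranking bit for bit", {
  co <- simulate_cohort(sim_config(n_per_region = 2500, n_regions = 3,
                                   seed = 17, sex = "female"))
  fam <- cvd_model("female")
  prac <- practical_recalibrate(fam, make_recalibration_table(co))
  ideal <- ideal_recalibrate(fam, co)
  for (r in unique(co$region)) {
    cr <- co[co$region == r, ]
    # per submodel the recalibrated risk is a strictly monotone transform
    # of the original risk, so within-region C is bit-identical
    for (k in c("IHD", "IS", "HS")) {
      st <- cvdrisk:::outcome_status(cr$event, k)
      col <- paste0("risk_", tolower(k))
      c_orig <- harrell_c(predict_cvd_risk(cr, fam)[[col]], cr$time, st)$c
      c_prac <- harrell_c(predict_cvd_risk(cr, prac, region = region)[[col]],
                          cr$time, st)$c
      c_ideal <- harrell_c(predict_cvd_risk(cr, ideal, region = region)[[col]],
                           cr$time, st)$c
      expect_identical(c_prac, c_orig)
      expect_identical(c_ideal, c_orig)
    }
    # the combined risk is reweighted across causes, so within-region C
    # can move, but only marginally
    st <- cvdrisk:::outcome_status(cr$event, "CVD")
    c_orig <- harrell_c(predict_cvd_risk(cr, fam)$risk_cvd, cr$time, st)$c
    c_ideal <- harrell_c(predict_cvd_risk(cr, ideal, region = region)$risk_cvd,
                         cr$time, st)$c
    expect_lt(abs(c_ideal - c_orig), 0.005)
  }
})

test_that("pooled concordance orders original <= practical <= ideal on region-shifted cohorts", {
  co <- simulate_cohort(sim_config(n_per_region = 4000, n_regions = 5,
                                   seed = 29, sex = "female"))
  fam <- cvd_model("female")
  prac <- practical_recalibrate(fam, make_recalibration_table(co))
  ideal <- ideal_recalibrate(fam, co)
  st <- cvdrisk:::outcome_status(co$event, "CVD")
  c_orig <- harrell_c(predict_cvd_risk(co, fam)$risk_cvd, co$time, st)$c
  c_prac <- harrell_c(predict_cvd_risk(co, prac, region = region)$risk_cvd,
                      co$time, st)$c
  c_ideal <- harrell_c(predict_cvd_risk(co, ideal, region = region)$risk_cvd,
                       co$time, st)$c
  noise <- 0.005
  expect_gte(c_prac, c_orig - noise)
  expect_gte(c_ideal, c_prac - noise)
  # region-varying baselines make recalibration genuinely informative
  expect_gt(c_ideal, c_orig)
})

test_that("recalibrated families survive the JSON round trip", {
  co <- simulate_cohort(sim_config(n_per_region = 800, n_regions = 2,
                                   seed = 71, sex = "male"))
  fam <- ideal_recalibrate(cvd_model("male"), co)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_family(fam, path)
  fam2 <- read_model_family(path)
  expect_equal(fam2$s0_overrides, fam$s0_overrides, tolerance = 1e-15)
  expect_identical(fam2$recalibration$method, "ideal")
  profs <- random_profiles(200, "male", seed = 2)
  expect_identical(
    predict_cvd_risk(profs, fam, region = rep(c("1", "2"), 100)),
    predict_cvd_risk(profs, fam2, region = rep(c("1", "2"), 100)))
})
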