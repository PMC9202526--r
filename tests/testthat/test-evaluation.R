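test_that("Harrell C handles the degenerate conventions", {
  # identical risks: every usable pair is a risk tie, C = 0.5
  expect_equal(harrell_c(rep(0.2, 8), time = 1:8,
                         status = rep(1, 8))$c, 0.5)
  # risks strictly decreasing in event time, no censoring: perfect
  # discrimination
  tt <- c(2, 5, 1, 9, 4, 7)
  expect_equal(harrell_c(1 / tt, time = tt, status = rep(1, 6))$c, 1)
})

test_that("Harrell C equals explicit pair enumeration on a censored fixture", {
  risks <- c(0.30, 0.40, 0.10, 0.70, 0.40, 0.05)
  tt <- c(2.0, 4.0, 9.0, 1.0, 6.0, 8.0)
  st <- c(1, 0, 1, 1, 1, 0)
  oracle <- oracle_harrell_c(risks, tt, st)
  got <- harrell_c(risks, tt, st)
  expect_equal(got$c, oracle$c, tolerance = 1e-12)
  expect_identical(got$n_pairs, oracle$n_pairs)
  expect_true(got$conf.low < got$c && got$c < got$conf.high)
})

test_that("Harrell C is invariant under strictly monotone risk transforms", {
  set.seed(42)
  n <- 300
  risks <- runif(n)
  tt <- rexp(n, 0.1 * (1 + 2 * risks))
  st <- as.integer(tt < 8)
  tt <- pmin(tt, 8 + runif(n))
  c1 <- harrell_c(risks, tt, st)$c
  expect_identical(harrell_c(qlogis(risks), tt, st)$c, c1)
  expect_identical(harrell_c(risks^3, tt, st)$c, c1)
})

test_that("Nam-D'Agostino chi-square matches hand computation on 3 groups", {
  # 30 subjects in three well-separated risk bands; KM per band computed
  # by an independent product-limit oracle
  set.seed(8)
  risks <- rep(c(0.05, 0.20, 0.60), each = 10) + runif(30, 0, 0.01)
  tt <- c(12, 13, 11, 14, 12.5, 11.5, 13.5, 12.2, 8, 6,       # low risk
          3, 12, 11, 5, 13, 7, 11.5, 12.8, 9, 14,             # medium
          1, 2, 12, 3, 0.5, 4, 11, 6, 2.5, 13)                # high
  st <- c(0, 0, 0, 0, 0, 0, 0, 0, 1, 0,
          1, 0, 0, 1, 0, 0, 0, 0, 1, 0,
          1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  nd <- nam_dagostino(risks, tt, st, horizon = 10, groups = 3)
  chi2_oracle <- 0
  for (g in 1:3) {
    ix <- (g - 1) * 10 + 1:10
    km <- oracle_km_risk(tt[ix], st[ix], 10)
    pbar <- mean(risks[ix])
    chi2_oracle <- chi2_oracle + 10 * (km - pbar)^2 / (pbar * (1 - pbar))
  }
  expect_equal(nd$chi2, chi2_oracle, tolerance = 1e-10)
  expect_identical(nd$df, 2L)
  expect_equal(nd$p.value, pchisq(chi2_oracle, 2, lower.tail = FALSE))
})

test_that("Nam-D'Agostino is 0 under exact calibration and grows with miscalibration", {
  # large simulated cohort from the evaluated model itself: chi2 should be
  # of the order of its degrees of freedom
  fam <- cvd_model("female")
  cfg <- sim_config(n_per_region = 20000, n_regions = 1, seed = 31,
                    sex = "female", hazard_multipliers = matrix(1, 1, 3),
                    death_rate = 0, unspecified_fraction = 0,
                    loss_fraction = 0)
  co <- simulate_cohort(cfg)
  pred <- predict_cvd_risk(co, fam)
  st <- cvdrisk:::outcome_status(co$event, "IHD")
  nd_ok <- nam_dagostino(pred$risk_ihd, co$time, st)
  expect_lt(nd_ok$chi2, 3 * 9)
  expect_gt(nd_ok$p.value, 1e-4)
  # doubling the predictions must blow the statistic up
  nd_bad <- nam_dagostino(pmin(2 * pred$risk_ihd, 0.999), co$time, st)
  expect_gt(nd_bad$chi2, 10 * nd_ok$chi2)
  # calibration table deciles partition the cohort
  tbl <- calibration_table(pred$risk_ihd, co$time, st)
  expect_identical(sum(tbl$n), nrow(co))
  expect_identical(nrow(tbl), 10L)
})

test_that("relative IDI matches its definition on a printed fixture", {
  # 8 subjects: 4 events by the horizon, 4 event-free at the horizon
  base <- c(0.30, 0.20, 0.25, 0.15, 0.10, 0.12, 0.08, 0.05)
  new <- c(0.40, 0.30, 0.20, 0.25, 0.05, 0.10, 0.06, 0.04)
  tt <- c(3, 5, 7, 9, 11, 12, 13, 14)
  st <- c(1, 1, 1, 1, 0, 0, 0, 0)
  slope_base <- mean(base[1:4]) - mean(base[5:8])
  slope_new <- mean(new[1:4]) - mean(new[5:8])
  out <- relative_idi(base, new, tt, st)
  expect_equal(out$idi, slope_new - slope_base, tolerance = 1e-12)
  expect_equal(out$relative_idi, 100 * (slope_new - slope_base) / slope_base,
               tolerance = 1e-12)
  # identical models: exactly zero improvement
  expect_identical(relative_idi(base, base, tt, st)$idi, 0)
  # base slope 0.10 with IDI 0.01 is a relative IDI of 10%
  b2 <- c(0.15, 0.15, 0.05, 0.05); n2 <- c(0.16, 0.16, 0.05, 0.05)
  out2 <- relative_idi(b2, n2, c(1, 2, 11, 12), c(1, 1, 0, 0))
  expect_equal(out2$base_slope, 0.10, tolerance = 1e-12)
  expect_equal(out2$idi, 0.01, tolerance = 1e-12)
  expect_equal(out2$relative_idi, 10, tolerance = 1e-9)
  # antisymmetry of the absolute improvement
  expect_equal(relative_idi(new, base, tt, st)$idi, -out$idi,
               tolerance = 1e-12)
  # subjects censored before the horizon are excluded from both means
  st3 <- c(1, 1, 1, 1, 0, 0, 0, 0); tt3 <- c(3, 5, 7, 9, 4, 12, 13, 14)
  out3 <- relative_idi(base, new, tt3, st3)
  expect_identical(out3$n_event_free, 3L)
  expect_error(relative_idi(base, new, tt, rep(0, 8)), "No events")
})

test_that("discrimination weakens in a narrow age stratum when age drives risk", {
  co <- simulate_cohort(sim_config(n_per_region = 8000, n_regions = 2,
                                   seed = 77, sex = "female"))
  fam <- cvd_model("female")
  ev_all <- evaluate_model(co, fam, "CVD", use_region = FALSE)
  old <- co[co$age >= 65, ]
  ev_old <- evaluate_model(old, fam, "CVD", use_region = FALSE)
  expect_lt(ev_old$harrell_c$c, ev_all$harrell_c$c)
  expect_identical(ev_all$n, nrow(co))
})

test_that("internal-external cross-validation pools per-region concordances", {
  co <- simulate_cohort(sim_config(n_per_region = 1500, n_regions = 3,
                                   seed = 55, sex = "female"))
  cv <- internal_external_cv(co, "IHD")
  expect_identical(nrow(cv$per_region), 3L)
  w <- 1 / cv$per_region$std.error^2
  expect_equal(cv$pooled$c, sum(w * cv$per_region$c) / sum(w),
               tolerance = 1e-12)
  expect_equal(cv$pooled$std.error, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_true(all(cv$per_region$c > 0.6))  # informative model discriminates

  # a model fitted to pure noise has no discrimination: pooled C near 0.5
  null_fam <- make_null_family("female")
  co0 <- simulate_cohort(sim_config(n_per_region = 1500, n_regions = 3,
                                    seed = 56, sex = "female",
                                    families = list(female = null_fam)))
  cv0 <- internal_external_cv(co0, "IHD")
  expect_lt(abs(cv0$pooled$c - 0.5), 0.03)
  expect_error(internal_external_cv(co[co$region != "3", ], "IHD"),
               "at least 3 regions")
})
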