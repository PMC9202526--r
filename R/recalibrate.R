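#' Validate a recalibration table
#'
#' Cross-sectional summaries consumed by practical recalibration: one row
#' per region x sex x 5-year age band (within 30-79) holding the band's
#' population share, the mean of each of the seven predictors, and the
#' annual incidence (events per person-year) of each outcome in columns
#' `incidence_ihd`, `incidence_is`, `incidence_hs`.
#'
#' @param table A data frame.
#' @return The table as a validated tibble.
#' @export
validate_recalibration_table <- function(table) {
  table <- tibble::as_tibble(table)
  needed <- c("region", "sex", "age_group", "population_share",
              cvd_predictors, paste0("incidence_", tolower(cvd_outcomes)))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    abort(paste0("Recalibration table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  inc <- paste0("incidence_", tolower(cvd_outcomes))
  for (col in inc) {
    if (any(table[[col]] < 0)) abort(sprintf("`%s` must be non-negative.", col))
  }
  shares <- dplyr::summarise(
    dplyr::group_by(table, .data$region, .data$sex),
    total = sum(.data$population_share), .groups = "drop")
  off <- abs(shares$total - 1) > 1e-6
  if (any(off)) {
    abort(sprintf(
      "Population shares must sum to 1 within region x sex (region %s, sex %s sums to %.4f).",
      shares$region[off][1], shares$sex[off][1], shares$total[off][1]))
  }
  table
}

#' Practical recalibration from cross-sectional summaries
#'
#' Replaces a region's 10-year baseline survival per outcome using only
#' age-group summary data, the mechanism used by the WHO CVD risk charts:
#' for each age band g the model's expected 10-year cumulative hazard at
#' the band's mean-covariate profile is
#' \eqn{\hat H_g = \exp(LP_g) (-\ln s_0)}, the observed cumulative hazard
#' is \eqn{H_g = 10 \lambda_g} from the band's annual incidence
#' \eqn{\lambda_g}, and the correction factor is the population-share
#' weighted ratio \eqn{c = \sum_g w_g H_g / \sum_g w_g \hat H_g}. The
#' regional baseline survival becomes \eqn{s_0^c}; the regression
#' coefficients are untouched. If annual incidences are annual risks
#' rather than person-year rates, set `incidence_scale = "risk"` to use
#' \eqn{H_g = -10 \ln(1 - \lambda_g)}.
#'
#' @param family A [model_family()].
#' @param table A [validate_recalibration_table()]-conformant data frame.
#' @param regions Regions to recalibrate; default all regions in `table`.
#' @param incidence_scale `"rate"` (events per person-year; default) or
#'   `"risk"` (annual risk).
#' @return The family with per-region baseline-survival overrides and the
#'   correction factors recorded in `$recalibration` (method
#'   `"practical"`).
#' @export
practical_recalibrate <- function(family, table, regions = NULL,
                                  incidence_scale = c("rate", "risk")) {
  stopifnot(inherits(family, "cvd_model_family"))
  incidence_scale <- match.arg(incidence_scale)
  table <- validate_recalibration_table(table)
  table <- table[table$sex == family$sex, ]
  if (nrow(table) == 0L) {
    abort(sprintf("Recalibration table has no rows for sex \"%s\".", family$sex))
  }
  regions <- regions %||% unique(as.character(table$region))
  missing_regions <- setdiff(regions, unique(as.character(table$region)))
  if (length(missing_regions)) {
    abort(paste0("Recalibration table lacks region(s): ",
                 paste(missing_regions, collapse = ", ")))
  }

  overrides <- list()
  factors <- list()
  for (r in regions) {
    tr <- table[as.character(table$region) == r, ]
    # Band mean covariates act as one profile per band.
    prof <- tibble::tibble(sex = family$sex, age = tr$age, sbp = tr$sbp,
                           dbp = tr$dbp, bp_treatment = tr$bp_treatment,
                           daily_smoker = tr$daily_smoker,
                           diabetes = tr$diabetes, waist = tr$waist)
    for (k in cvd_outcomes) {
      cs <- get_submodel(family, k)
      lam <- tr[[paste0("incidence_", tolower(k))]]
      H_obs <- switch(incidence_scale,
                      rate = 10 * lam,
                      risk = -10 * log(1 - lam))
      # Binary band means are prevalences in [0,1]; bypass the 0/1 check
      # by computing the linear predictor from model units directly.
      u <- model_units(prof)
      beta <- setNames(cs$terms$beta_main, cs$terms$predictor)
      gamma <- setNames(cs$terms$beta_age_interaction, cs$terms$predictor)
      others <- setdiff(cvd_predictors, "age")
      lp <- drop(u %*% beta) +
        drop((u[, others, drop = FALSE] * u[, "age"]) %*% gamma[others])
      H_hat <- exp(lp) * (-log(cs$s0_10))
      w <- tr$population_share
      denom <- sum(w * H_hat)
      if (denom <= 0) {
        abort(sprintf("Model-expected hazard is zero for %s in region %s.", k, r))
      }
      cfac <- sum(w * H_obs) / denom
      overrides[[length(overrides) + 1L]] <- tibble::tibble(
        region = r, outcome = k, s0_10 = cs$s0_10^cfac)
      factors[[length(factors) + 1L]] <- tibble::tibble(
        region = r, outcome = k, correction = cfac)
    }
  }
  family$s0_overrides <- dplyr::bind_rows(overrides)
  family$recalibration <- list(method = "practical",
                               factors = dplyr::bind_rows(factors))
  family
}

#' Ideal recalibration from observed 10-year risks
#'
#' Replaces a region's baseline survival per outcome so that the mean
#' predicted 10-year risk over the region's subjects equals the observed
#' 10-year risk (Kaplan-Meier at the horizon, competing events censored):
#' solves \eqn{mean_i [1 - s^{\exp(LP_i)}] = risk_{obs}} for s by monotone
#' 1-D root finding on (0, 1).
#'
#' @param family A [model_family()].
#' @param cohort A cohort table containing the target regions.
#' @param regions Regions to recalibrate; default all in `cohort`.
#' @param horizon Risk horizon in years.
#' @param tol Tolerance on the mean-risk gap at the root.
#' @return The family with overrides recorded (method `"ideal"`). The
#'   correction factor reported per region x outcome is
#'   \eqn{\log(s_{new}) / \log(s_0)}, the implied cumulative-hazard
#'   multiplier.
#' @export
ideal_recalibrate <- function(family, cohort, regions = NULL, horizon = 10,
                              tol = 1e-10) {
  stopifnot(inherits(family, "cvd_model_family"))
  cohort <- validate_cohort(cohort)
  if (any(cohort$sex != family$sex)) {
    abort("Cohort sex does not match the model family.")
  }
  regions <- regions %||% unique(as.character(cohort$region))
  overrides <- list()
  factors <- list()
  for (r in regions) {
    cr <- cohort[as.character(cohort$region) == r, ]
    if (nrow(cr) == 0L) abort(sprintf("Region %s not present in the cohort.", r))
    for (k in cvd_outcomes) {
      cs <- get_submodel(family, k)
      status <- outcome_status(cr$event, k)
      obs <- km_observed_risk(cr$time, status, horizon)$observed
      elp <- exp(linear_predictor(cr, cs))
      if (obs <= 0) {
        warn(sprintf("Observed %g-year %s risk is 0 in region %s; baseline survival set to 1.",
                     horizon, k, r))
        s_new <- 1 - 1e-12
      } else if (obs >= 1) {
        abort(sprintf("Observed %s risk is 1 in region %s; no root in (0, 1).", k, r))
      } else {
        gap <- function(s) mean(1 - s^elp) - obs
        # gap is strictly decreasing in s, positive at 0+, negative at 1-
        # whenever 0 < obs < 1.
        s_new <- uniroot(gap, lower = 1e-12, upper = 1 - 1e-12,
                         tol = .Machine$double.eps^0.75)$root
        if (abs(gap(s_new)) > max(tol, 1e-8)) {
          abort(sprintf("Root finding failed for %s in region %s (gap %.3g).",
                        k, r, gap(s_new)))
        }
      }
      overrides[[length(overrides) + 1L]] <- tibble::tibble(
        region = r, outcome = k, s0_10 = s_new)
      factors[[length(factors) + 1L]] <- tibble::tibble(
        region = r, outcome = k, correction = log(s_new) / log(cs$s0_10))
    }
  }
  family$s0_overrides <- dplyr::bind_rows(overrides)
  family$recalibration <- list(method = "ideal",
                               factors = dplyr::bind_rows(factors))
  family
}
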