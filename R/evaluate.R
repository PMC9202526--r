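#' Harrell concordance for a predicted-risk marker
#'
#' Probability that, of a usable pair (an event subject paired with a
#' subject whose event or censoring comes later), the subject with the
#' higher predicted risk has the earlier event. Tied risks count 0.5. The
#' 95% CI uses the asymptotic standard error of the concordance estimator.
#'
#' @param risks Numeric vector of predicted risks (any strictly monotone
#'   transform of risk gives the same value).
#' @param time Follow-up times.
#' @param status 0/1 event indicators.
#' @return One-row tibble: `c` (concordance), `std.error`, `conf.low`,
#'   `conf.high`, `n_pairs` (comparable pairs).
#' @export
#' @examples
#' harrell_c(c(0.9, 0.5, 0.1), time = c(1, 2, 3), status = c(1, 1, 1))
harrell_c <- function(risks, time, status) {
  if (length(risks) != length(time) || length(time) != length(status)) {
    abort("`risks`, `time`, `status` must have equal lengths.")
  }
  cf <- survival::concordance(survival::Surv(time, status) ~ risks,
                              reverse = TRUE)
  counts <- as.numeric(cf$count)
  n_pairs <- sum(counts[1:3])                  # concordant + discordant + tied x
  if (n_pairs < 2) abort("Fewer than 2 comparable pairs: concordance undefined.")
  se <- sqrt(cf$var)
  z <- qnorm(0.975)
  tibble::tibble(
    c = as.numeric(cf$concordance), std.error = se,
    conf.low = max(0, cf$concordance - z * se),
    conf.high = min(1, cf$concordance + z * se),
    n_pairs = n_pairs
  )
}

# Decile (or g-tile) group index of predicted risks, ties going to the
# lower group: right-closed quantile intervals.
risk_groups <- function(risks, groups = 10) {
  breaks <- quantile(risks, probs = seq(0, 1, length.out = groups + 1),
                     names = FALSE, type = 7)
  breaks <- unique(breaks)
  if (length(breaks) < 2) abort("Predicted risks are all identical; cannot form groups.")
  g <- cut(risks, breaks = breaks, include.lowest = TRUE, right = TRUE,
           labels = FALSE)
  list(group = g, n_groups = length(breaks) - 1L)
}

# Kaplan-Meier observed risk (1 - S(t)) at the horizon, with a Greenwood
# CI, for one group of subjects.
km_observed_risk <- function(time, status, horizon) {
  sf <- survival::survfit(survival::Surv(time, status) ~ 1, conf.type = "log-log")
  sm <- summary(sf, times = horizon, extend = TRUE)
  tibble::tibble(
    observed = 1 - sm$surv,
    obs.low = 1 - ifelse(is.na(sm$upper), 1, sm$upper),
    obs.high = 1 - ifelse(is.na(sm$lower), 0, sm$lower)
  )
}

#' Decile calibration table
#'
#' Groups subjects by deciles of predicted risk and compares, per decile,
#' the mean predicted 10-year risk with the Kaplan-Meier observed 10-year
#' risk (with CI). This is the table behind the calibration plots and the
#' Nam-D'Agostino statistic.
#'
#' @inheritParams harrell_c
#' @param horizon Risk horizon in years.
#' @param groups Number of risk groups (deciles by default).
#' @return A tibble of class `cvd_calibration` with one row per group:
#'   `group`, `n`, `n_events`, `predicted` (mean), `observed` (KM),
#'   `obs.low`, `obs.high`.
#' @export
calibration_table <- function(risks, time, status, horizon = 10, groups = 10) {
  if (any(risks < 0 | risks > 1)) abort("`risks` must be probabilities in [0, 1].")
  rg <- risk_groups(risks, groups)
  tbl <- dplyr::bind_rows(lapply(seq_len(rg$n_groups), function(g) {
    ix <- which(rg$group == g)
    if (!length(ix)) abort(sprintf("Risk group %d is empty.", g))
    km <- km_observed_risk(time[ix], status[ix], horizon)
    tibble::tibble(group = g, n = length(ix),
                   n_events = sum(status[ix] == 1 & time[ix] <= horizon),
                   predicted = mean(risks[ix]),
                   observed = km$observed, obs.low = km$obs.low,
                   obs.high = km$obs.high)
  }))
  class(tbl) <- c("cvd_calibration", class(tbl))
  attr(tbl, "horizon") <- horizon
  tbl
}

#' Nam-D'Agostino calibration test
#'
#' Survival-adapted goodness-of-fit chi-square across risk deciles:
#' \deqn{\chi^2 = \sum_g n_g (KM_g - \bar p_g)^2 / (\bar p_g (1 - \bar p_g)),}
#' where \eqn{KM_g} is the Kaplan-Meier observed risk at the horizon and
#' \eqn{\bar p_g} the mean predicted risk in decile g, on groups - 1
#' degrees of freedom.
#'
#' @inheritParams calibration_table
#' @return One-row tibble: `chi2`, `df`, `p.value`, plus the calibration
#'   table as attribute `"table"`.
#' @export
nam_dagostino <- function(risks, time, status, horizon = 10, groups = 10) {
  tbl <- calibration_table(risks, time, status, horizon = horizon,
                           groups = groups)
  if (any(tbl$predicted <= 0 | tbl$predicted >= 1)) {
    abort("Degenerate group: mean predicted risk of 0 or 1.")
  }
  chi2 <- sum(tbl$n * (tbl$observed - tbl$predicted)^2 /
                (tbl$predicted * (1 - tbl$predicted)))
  df <- nrow(tbl) - 1L
  out <- tibble::tibble(chi2 = chi2, df = df,
                        p.value = pchisq(chi2, df, lower.tail = FALSE))
  attr(out, "table") <- tbl
  out
}

#' Integrated discrimination improvement of one risk model over another
#'
#' IDI is the gain in discrimination slope: (mean new-model risk in
#' subjects with an event by the horizon minus mean in event-free
#' subjects) minus the same difference for the base model. The relative
#' IDI expresses it as a percentage of the base model's slope. Subjects
#' censored before the horizon without an event are excluded from both
#' means.
#'
#' @param base_risks,new_risks Predicted risks from the two models, over
#'   the same subjects.
#' @inheritParams calibration_table
#' @return One-row tibble: `idi`, `base_slope`, `new_slope`,
#'   `relative_idi` (percent), `n_events`, `n_event_free`.
#' @export
relative_idi <- function(base_risks, new_risks, time, status, horizon = 10) {
  if (length(base_risks) != length(new_risks)) {
    abort("Risk vectors must cover the same subjects.")
  }
  is_event <- status == 1 & time <= horizon
  is_free <- time >= horizon & !is_event
  usable <- is_event | is_free
  if (!any(is_event)) abort("No events by the horizon: IDI undefined.")
  if (!any(is_free)) abort("No event-free subjects at the horizon: IDI undefined.")
  slope <- function(r) mean(r[is_event]) - mean(r[is_free])
  base_slope <- slope(base_risks)
  new_slope <- slope(new_risks)
  idi <- new_slope - base_slope
  tibble::tibble(
    idi = idi, base_slope = base_slope, new_slope = new_slope,
    relative_idi = 100 * idi / base_slope,
    n_events = sum(is_event), n_event_free = sum(is_free)
  )
}

#' Evaluate a model family on a cohort
#'
#' Computes discrimination (Harrell C with CI), calibration (decile table
#' and Nam-D'Agostino test), and the predicted risks, for total CVD or one
#' submodel outcome. Total-CVD evaluation counts unspecified-stroke events
#' as events even though no submodel predicts them.
#'
#' @param cohort A validated cohort table (single sex, matching the
#'   family).
#' @param family A [model_family()], possibly recalibrated.
#' @param outcome `"CVD"` (default) or one of `"IHD"`, `"IS"`, `"HS"`.
#' @param use_region Use the cohort's `region` column for recalibrated
#'   per-region baseline survivals.
#' @param horizon,groups Passed to the calibration machinery.
#' @return An object of class `cvd_evaluation`: a list with `harrell_c`,
#'   `nam_dagostino`, `calibration`, `outcome`, `n`, `n_events`, and the
#'   per-subject `risks`.
#' @export
evaluate_model <- function(cohort, family, outcome = c("CVD", "IHD", "IS", "HS"),
                           use_region = TRUE, horizon = 10, groups = 10) {
  outcome <- match.arg(outcome)
  cohort <- validate_cohort(cohort)
  pred <- if (use_region) {
    predict_cvd_risk(cohort, family, region = region)
  } else {
    predict_cvd_risk(cohort, family)
  }
  risks <- switch(outcome, CVD = pred$risk_cvd, IHD = pred$risk_ihd,
                  IS = pred$risk_is, HS = pred$risk_hs)
  status <- outcome_status(cohort$event, outcome)
  hc <- harrell_c(risks, cohort$time, status)
  nd <- nam_dagostino(risks, cohort$time, status, horizon = horizon,
                      groups = groups)
  structure(
    list(outcome = outcome, harrell_c = hc, nam_dagostino = nd,
         calibration = attr(nd, "table"), n = nrow(cohort),
         n_events = sum(status == 1 & cohort$time <= horizon),
         horizon = horizon, risks = risks),
    class = "cvd_evaluation"
  )
}

#' @export
print.cvd_evaluation <- function(x, ...) {
  cat(sprintf("<cvd_evaluation> %s: n = %d, events by %g y = %d\n",
              x$outcome, x$n, x$horizon, x$n_events))
  cat(sprintf("  Harrell C = %.3f (95%% CI %.3f-%.3f)\n",
              x$harrell_c$c, x$harrell_c$conf.low, x$harrell_c$conf.high))
  cat(sprintf("  Nam-D'Agostino chi2 = %.1f on %d df (p = %.3g)\n",
              x$nam_dagostino$chi2, x$nam_dagostino$df,
              x$nam_dagostino$p.value))
  invisible(x)
}

#' @rdname tidy.cvd_cox_fit
#' @export
tidy.cvd_evaluation <- function(x, ...) {
  x$calibration
}

#' @rdname tidy.cvd_cox_fit
#' @export
glance.cvd_evaluation <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n = x$n, n_events = x$n_events,
    harrell_c = x$harrell_c$c, c_conf.low = x$harrell_c$conf.low,
    c_conf.high = x$harrell_c$conf.high,
    nd_chi2 = x$nam_dagostino$chi2, nd_df = x$nam_dagostino$df,
    nd_p.value = x$nam_dagostino$p.value
  )
}

#' Internal-external cross-validation of a submodel
#'
#' Leave-one-region-out validation: each region is held out in turn, the
#' submodel is refit on the remaining regions, and Harrell C is computed
#' in the held-out region. Per-region concordances are pooled by
#' inverse-variance weighting on the C scale.
#'
#' @inheritParams fit_stratified_cox
#' @return A list with `per_region` (tibble: region, c, std.error,
#'   conf.low, conf.high, n, n_events) and `pooled` (one-row tibble).
#' @export
internal_external_cv <- function(cohort, outcome = c("IHD", "IS", "HS"),
                                 interactions = TRUE) {
  outcome <- match.arg(outcome)
  cohort <- validate_cohort(cohort)
  regions <- unique(as.character(cohort$region))
  if (length(regions) < 3L) {
    abort("Internal-external cross-validation needs at least 3 regions.")
  }
  per <- list()
  for (r in regions) {
    train <- cohort[cohort$region != r, ]
    test <- cohort[cohort$region == r, ]
    fit <- fit_stratified_cox(train, outcome, interactions = interactions)
    beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    Xt <- cox_design_matrix(test, interactions = interactions)
    risks <- 1 - fit$s0_10^exp(drop(Xt %*% beta))
    status <- outcome_status(test$event, outcome)
    hc <- tryCatch(harrell_c(risks, test$time, status),
                   error = function(e) NULL)
    if (is.null(hc) || !is.finite(hc$std.error) || hc$std.error == 0) {
      warn(sprintf("Region %s excluded from pooling (too few comparable pairs).", r))
      next
    }
    per[[r]] <- dplyr::mutate(hc, region = r, n = nrow(test),
                              n_events = sum(status), .before = 1)
  }
  per_region <- dplyr::bind_rows(per)
  w <- 1 / per_region$std.error^2
  pooled_c <- sum(w * per_region$c) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  z <- qnorm(0.975)
  list(
    per_region = per_region,
    pooled = tibble::tibble(
      c = pooled_c, std.error = pooled_se,
      conf.low = pooled_c - z * pooled_se,
      conf.high = pooled_c + z * pooled_se,
      n_regions = nrow(per_region)
    )
  )
}
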