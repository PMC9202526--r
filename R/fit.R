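cohort_events <- c("none", "IHD", "IS", "HS", "unspecified_stroke",
                   "death_other")

#' Validate a cohort table
#'
#' A cohort table has one row per subject with columns `id`, `region`,
#' `sex`, the seven predictors, `time` (years of follow-up, > 0), and
#' `event` (one of `none`, `IHD`, `IS`, `HS`, `unspecified_stroke`,
#' `death_other`). `time` is the time from baseline to the first CVD
#' diagnosis, death, loss to follow-up, or the administrative censoring
#' date, whichever comes first.
#'
#' @param cohort A data frame.
#' @return The cohort as a validated tibble.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  needed <- c("id", "region", "time", "event")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_profiles(cohort[setdiff(names(cohort), needed)])
  if (anyDuplicated(cohort$id)) {
    abort("Cohort must have one row per subject (`id` values repeat).")
  }
  if (!is.numeric(cohort$time) || any(!is.finite(cohort$time)) ||
      any(cohort$time <= 0)) {
    abort("`time` must be finite and > 0 for every subject.")
  }
  bad <- !cohort$event %in% cohort_events
  if (any(bad)) {
    abort(sprintf("Unknown event label \"%s\" (row %d). Allowed: %s.",
                  cohort$event[which(bad)[1]], which(bad)[1],
                  paste(cohort_events, collapse = ", ")))
  }
  cohort
}

# 0/1 event indicator for one target outcome under the cause-specific
# convention: competing CVD types and deaths censor at their time.
outcome_status <- function(event, outcome) {
  if (outcome == "CVD") {
    as.integer(event %in% c("IHD", "IS", "HS", "unspecified_stroke"))
  } else {
    as.integer(event == outcome)
  }
}

#' Fit one cause-specific submodel by region-stratified Cox regression
#'
#' Maximizes the region-stratified Cox partial likelihood (Efron tie
#' handling, Newton-Raphson with step-halving) for one outcome, treating
#' other first CVD events and deaths as censoring at their occurrence time
#' (cause-specific hazards). The design has the seven predictors in
#' centered model units plus, optionally, the six age-by-predictor
#' interactions, so coefficients are directly comparable to the published
#' log-hazard-ratios. Per-region 10-year baseline survivals are obtained
#' from the Breslow cumulative baseline hazard at the covariate origin and
#' pooled across regions weighted by the number of events by 10 years.
#'
#' @param cohort A [validate_cohort()]-conformant data frame containing a
#'   single sex.
#' @param outcome `"IHD"`, `"IS"`, or `"HS"`.
#' @param interactions Include age-by-predictor interaction terms.
#' @param horizon Risk horizon in years for baseline survival (fixed at 10
#'   in the published models).
#' @param init,max_iter,grad_tol,ll_tol Optimizer controls: initial values,
#'   iteration cap, score tolerance (max absolute gradient), and relative
#'   log-likelihood change tolerance.
#' @return An object of class `cvd_cox_fit` with elements `coefficients`
#'   (tibble: term, estimate, std.error, hazard ratio and 95% CI),
#'   `vcov`, `s0_by_region`, pooled `s0_10`, and convergence diagnostics.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_per_region = 500, n_regions = 3,
#'                                      seed = 7, sex = "female"))
#' fit <- fit_stratified_cox(cohort, "IHD")
#' tidy(fit)
#' }
fit_stratified_cox <- function(cohort, outcome = c("IHD", "IS", "HS"),
                               interactions = TRUE, horizon = 10,
                               init = NULL, max_iter = 100L,
                               grad_tol = 1e-7, ll_tol = 1e-9) {
  outcome <- match.arg(outcome)
  cohort <- validate_cohort(cohort)
  sex <- unique(cohort$sex)
  if (length(sex) != 1L) {
    abort("Cohort contains both sexes; fit each sex separately.")
  }
  if (length(unique(cohort$region)) < 2L) {
    warn("Fewer than 2 regions: the stratified fit reduces to an unstratified one.")
  }
  X <- cox_design_matrix(cohort, interactions = interactions)
  status <- outcome_status(cohort$event, outcome)
  eng <- cox_newton(X, cohort$time, status, cohort$region, init = init,
                    max_iter = max_iter, grad_tol = grad_tol, ll_tol = ll_tol)
  s0_tbl <- cox_breslow_s0(eng, horizon = horizon)
  zero_ev <- s0_tbl$events_by_horizon == 0
  if (any(zero_ev)) {
    warn(paste0("Region(s) with no ", outcome, " events by ", horizon,
                " years (baseline survival set to 1): ",
                paste(s0_tbl$region[zero_ev], collapse = ", ")))
  }
  s0_pooled <- pool_baseline_survival(
    setNames(s0_tbl$s0_10, s0_tbl$region),
    setNames(s0_tbl$events_by_horizon, s0_tbl$region)
  )
  ci <- qnorm(0.975)
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(eng$beta),
    std.error = unname(eng$se),
    hr = exp(unname(eng$beta)),
    conf.low = exp(unname(eng$beta) - ci * unname(eng$se)),
    conf.high = exp(unname(eng$beta) + ci * unname(eng$se))
  )
  structure(
    list(outcome = outcome, sex = sex, interactions = interactions,
         horizon = horizon, coefficients = coefs, vcov = eng$vcov,
         s0_by_region = s0_tbl, s0_10 = s0_pooled,
         loglik = eng$loglik, iterations = eng$iterations,
         max_gradient = eng$max_gradient, converged = eng$converged,
         infinite_variance = eng$infinite_variance,
         n = nrow(cohort), n_events = sum(status)),
    class = "cvd_cox_fit"
  )
}

#' @export
print.cvd_cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cvd_cox_fit> %s (%s), %d subjects, %d events; pooled S0(%g) = %.4f\n",
    x$outcome, x$sex, x$n, x$n_events, x$horizon, x$s0_10))
  cat(sprintf("  converged in %d iterations (max |gradient| %.2g)\n",
              x$iterations, x$max_gradient))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stratified Cox fit
#'
#' @param x A `cvd_cox_fit`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate` (log-hazard-ratio),
#'   `std.error`, `hr`, `conf.low`, `conf.high` (95% CI on the hazard-ratio
#'   scale).
#' @export
tidy.cvd_cox_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.cvd_cox_fit
#' @return `glance()` returns a one-row tibble of fit-level summaries.
#' @export
glance.cvd_cox_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, sex = x$sex, n = x$n, n_events = x$n_events,
    loglik = x$loglik, iterations = x$iterations,
    max_gradient = x$max_gradient, s0_10 = x$s0_10,
    converged = x$converged
  )
}

#' Per-region baseline survival at the horizon
#'
#' Evaluates the Breslow cumulative baseline hazard \eqn{H_{0r}(t)} at the
#' centered covariate origin within each region and returns
#' \eqn{s_{0r} = \exp(-H_{0r}(t))} together with the number of
#' target-outcome events observed by the horizon (the pooling weights). A
#' region with no events by the horizon has baseline survival 1.
#'
#' @inheritParams fit_stratified_cox
#' @param fit A converged `cvd_cox_fit` obtained on `cohort`.
#' @return Tibble with columns `region`, `s0_10`, `events_by_horizon`.
#' @export
estimate_baseline_survival <- function(cohort, fit, horizon = 10) {
  stopifnot(inherits(fit, "cvd_cox_fit"))
  cohort <- validate_cohort(cohort)
  X <- cox_design_matrix(cohort, interactions = fit$interactions)
  status <- outcome_status(cohort$event, fit$outcome)
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  eta <- drop(X %*% beta)
  out <- lapply(split(seq_len(nrow(cohort)), as.character(cohort$region)),
                function(ix) {
    tt <- cohort$time[ix]; ss <- status[ix]; ww <- exp(eta[ix])
    ord <- order(tt, decreasing = TRUE)
    tt <- tt[ord]; ss <- ss[ord]; ww <- ww[ord]
    cum0 <- cumsum(ww)
    r <- rle(tt)
    grp_end <- cumsum(r$lengths)
    grp_id <- rep(seq_along(r$lengths), r$lengths)
    ev_groups <- table(grp_id[ss == 1])
    gid <- as.integer(names(ev_groups))
    sel <- r$values[gid] <= horizon
    H0 <- if (any(sel)) sum(as.numeric(ev_groups)[sel] / cum0[grp_end[gid][sel]]) else 0
    tibble::tibble(s0_10 = exp(-H0),
                   events_by_horizon = sum(ss == 1 & tt <= horizon))
  })
  dplyr::bind_rows(out, .id = "region")
}

#' Pool per-region baseline survivals
#'
#' Event-count-weighted mean of regional baseline survivals:
#' \eqn{s_0 = \sum_r w_r s_{0r}} with \eqn{w_r} proportional to the number
#' of target-outcome events by 10 years in region r.
#'
#' @param per_region Named numeric vector of per-region `s0_10` values.
#' @param case_counts Named numeric vector of event counts by 10 years,
#'   same regions.
#' @return The pooled baseline survival.
#' @export
#' @examples
#' pool_baseline_survival(c(a = 0.92, b = 0.88), c(a = 3, b = 1))  # 0.91
pool_baseline_survival <- function(per_region, case_counts) {
  if (!setequal(names(per_region), names(case_counts))) {
    abort("`per_region` and `case_counts` must cover the same regions.")
  }
  case_counts <- case_counts[names(per_region)]
  if (any(case_counts < 0)) abort("Event counts must be non-negative.")
  total <- sum(case_counts)
  if (total <= 0) abort("Total event count is zero: pooled baseline survival undefined.")
  sum(per_region * case_counts) / total
}

#' Build a coefficient set from a fitted submodel
#'
#' Packages a converged fit as a [coef_set()] usable by the prediction
#' engine, with the pooled 10-year baseline survival.
#'
#' @param fit A `cvd_cox_fit` fitted with age interactions.
#' @return A `cvd_coef_set`.
#' @export
coef_set_from_fit <- function(fit) {
  stopifnot(inherits(fit, "cvd_cox_fit"))
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  hr_main <- exp(beta[cvd_predictors])
  names(hr_main) <- cvd_predictors
  others <- setdiff(cvd_predictors, "age")
  if (fit$interactions) {
    hr_int <- exp(beta[paste0("age:", others)])
    names(hr_int) <- others
  } else {
    hr_int <- setNames(rep(1, length(others)), others)
  }
  coef_set(fit$outcome, fit$sex, hr_main, hr_int, fit$s0_10)
}
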