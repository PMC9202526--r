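#' Linear predictor of one cause-specific submodel
#'
#' Computes, for each profile row, the centered linear predictor
#' \deqn{LP = \sum_p \beta_p u_p + \sum_{p \ne age} \gamma_p u_{age} u_p,}
#' where \eqn{u_p} is the predictor in centered model units (age per 5
#' years from 55, blood pressures per 10 mm Hg from 120/80, waist per 10 cm
#' from 80, binaries 0/1), \eqn{\beta_p} the main-effect log-hazard-ratio
#' and \eqn{\gamma_p} the age-interaction log-hazard-ratio (per 5 years of
#' age). At the reference profile the linear predictor is exactly 0.
#'
#' @param profiles Data frame of risk profiles (see [validate_profiles()]).
#' @param coefs A [coef_set()].
#' @return Numeric vector, one linear predictor per row.
#' @export
#' @examples
#' linear_predictor(reference_profile("female"), cvd_model("female")$submodels$IHD)
linear_predictor <- function(profiles, coefs) {
  stopifnot(inherits(coefs, "cvd_coef_set"))
  profiles <- validate_profiles(profiles, sex = coefs$sex)
  if (nrow(profiles) == 0L) return(numeric(0))
  u <- model_units(profiles)
  beta <- setNames(coefs$terms$beta_main, coefs$terms$predictor)
  gamma <- setNames(coefs$terms$beta_age_interaction, coefs$terms$predictor)
  lp <- drop(u %*% beta)
  others <- setdiff(cvd_predictors, "age")
  lp + drop((u[, others, drop = FALSE] * u[, "age"]) %*% gamma[others])
}

#' Ten-year risk from one cause-specific submodel
#'
#' Converts the linear predictor into an absolute 10-year risk through the
#' baseline survival: \eqn{risk = 1 - s_0(10)^{\exp(LP)}}.
#'
#' @inheritParams linear_predictor
#' @param s0_10 Optional baseline survival override (e.g., a recalibrated
#'   regional value); defaults to the coefficient set's pooled `s0_10`.
#'   Recycled to the number of rows.
#' @return Numeric vector of risks in (0, 1).
#' @export
predict_submodel_risk <- function(profiles, coefs, s0_10 = NULL) {
  s0 <- s0_10 %||% coefs$s0_10
  if (any(s0 <= 0 | s0 >= 1)) abort("`s0_10` must lie strictly inside (0, 1).")
  lp <- linear_predictor(profiles, coefs)
  1 - rep_len(s0, length(lp))^exp(lp)
}

#' Predict 10-year risks of IHD, ischemic stroke, hemorrhagic stroke, and
#' total CVD
#'
#' Applies the three cause-specific submodels and combines them by
#' conditional probability:
#' \deqn{Risk_{CVD} = 1 - (1 - Risk_{IHD})(1 - Risk_{IS})(1 - Risk_{HS}).}
#'
#' @param profiles Data frame of risk profiles; extra columns are carried
#'   through to the output.
#' @param family A [model_family()], e.g. from [cvd_model()].
#' @param region Optional region labels (a single value, or the bare name
#'   of a column of `profiles`). Used only when `family` carries
#'   recalibrated per-region baseline survivals; regions without an
#'   override fall back to the pooled baseline survival.
#' @param keep_lp Keep the per-outcome linear predictors as columns
#'   `lp_ihd`, `lp_is`, `lp_hs`.
#' @return The input tibble with columns `risk_ihd`, `risk_is`, `risk_hs`,
#'   `risk_cvd` appended (and linear predictors if `keep_lp`).
#' @export
#' @examples
#' predict_cvd_risk(reference_profile("female"), cvd_model("female"))
predict_cvd_risk <- function(profiles, family, region = NULL, keep_lp = FALSE) {
  stopifnot(inherits(family, "cvd_model_family"))
  profiles <- validate_profiles(profiles, sex = family$sex)
  region <- resolve_region(profiles, rlang::enquo(region))
  out <- profiles
  risks <- list()
  for (k in cvd_outcomes) {
    cs <- get_submodel(family, k)
    lp <- linear_predictor(profiles, cs)
    s0 <- if (is.null(region)) cs$s0_10 else s0_for(family, k, region)
    risks[[k]] <- 1 - rep_len(s0, length(lp))^exp(lp)
    if (keep_lp) out[[paste0("lp_", tolower(k))]] <- lp
  }
  out$risk_ihd <- risks$IHD
  out$risk_is <- risks$IS
  out$risk_hs <- risks$HS
  out$risk_cvd <- combine_cvd_risk(risks$IHD, risks$IS, risks$HS)
  out
}

#' Combine cause-specific risks into total CVD risk
#'
#' @param risk_ihd,risk_is,risk_hs Probabilities in `[0, 1]`.
#' @return `1 - (1 - risk_ihd) * (1 - risk_is) * (1 - risk_hs)`.
#' @export
combine_cvd_risk <- function(risk_ihd, risk_is, risk_hs) {
  1 - (1 - risk_ihd) * (1 - risk_is) * (1 - risk_hs)
}

# `region` may be NULL, a column name in `profiles` (bare or string), or a
# vector of labels recycled to nrow(profiles).
resolve_region <- function(profiles, quo) {
  if (rlang::quo_is_null(quo)) return(NULL)
  expr <- rlang::quo_get_expr(quo)
  if (rlang::is_symbol(expr) && rlang::as_string(expr) %in% names(profiles)) {
    return(profiles[[rlang::as_string(expr)]])
  }
  val <- rlang::eval_tidy(quo)
  if (is.null(val)) return(NULL)
  if (length(val) == 1L && is.character(val) && val %in% names(profiles)) {
    return(profiles[[val]])
  }
  rep_len(val, nrow(profiles))
}
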