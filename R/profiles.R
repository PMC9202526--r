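#' Validate a table of individual risk profiles
#'
#' A risk profile holds one individual's values for the seven predictors:
#' `age` (years), `sbp` and `dbp` (mm Hg), `bp_treatment`, `daily_smoker`,
#' `diabetes` (0/1 or logical), and `waist` (cm), plus `sex` (`"female"` or
#' `"male"`). Admissible ranges follow the derivation cohort's eligibility:
#' age 30-79; SBP 60-280 and DBP 30-200 mm Hg with SBP >= DBP; waist
#' 40-180 cm.
#'
#' @param profiles A data frame with one row per individual.
#' @param sex If given, every row's `sex` must equal it.
#' @return The validated profiles as a tibble, with binary columns coerced
#'   to 0/1 numeric.
#' @export
#' @examples
#' validate_profiles(reference_profile("female"))
validate_profiles <- function(profiles, sex = NULL) {
  profiles <- tibble::as_tibble(profiles)
  needed <- c("sex", cvd_predictors)
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols)) {
    abort(paste0("Profile table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(profiles) == 0L) {
    return(profiles)
  }
  bad_sex <- !profiles$sex %in% c("female", "male")
  if (any(bad_sex)) {
    abort(sprintf("Column `sex` must be \"female\" or \"male\" (first bad row: %d).",
                  which(bad_sex)[1]))
  }
  if (!is.null(sex) && any(profiles$sex != sex)) {
    abort(sprintf(
      "Profile sex does not match the model sex \"%s\" (first mismatch: row %d).",
      sex, which(profiles$sex != sex)[1]))
  }
  for (b in c("bp_treatment", "daily_smoker", "diabetes")) {
    v <- profiles[[b]]
    if (is.logical(v)) v <- as.numeric(v)
    if (!is.numeric(v) || anyNA(v) || !all(v %in% c(0, 1))) {
      abort(sprintf("Column `%s` must be 0/1 or logical with no missing values.", b))
    }
    profiles[[b]] <- v
  }
  check_range <- function(field, lo, hi) {
    v <- profiles[[field]]
    if (!is.numeric(v) || anyNA(v)) {
      abort(sprintf("Column `%s` must be numeric with no missing values.", field))
    }
    bad <- v < lo | v > hi
    if (any(bad)) {
      abort(sprintf("Column `%s` outside [%g, %g] (first bad row: %d, value %g).",
                    field, lo, hi, which(bad)[1], v[which(bad)[1]]))
    }
  }
  check_range("age", 30, 79)
  check_range("sbp", 60, 280)
  check_range("dbp", 30, 200)
  check_range("waist", 40, 180)
  bad_bp <- profiles$sbp < profiles$dbp
  if (any(bad_bp)) {
    abort(sprintf("`sbp` must be >= `dbp` (first bad row: %d).", which(bad_bp)[1]))
  }
  profiles
}

#' Reference risk profile
#'
#' The individual with every continuous predictor at its centering constant
#' (age 55, SBP 120, DBP 80, waist 80) and all binary predictors absent.
#' Every submodel's linear predictor is exactly zero here, so the predicted
#' 10-year risk equals `1 - s0_10`.
#'
#' @param sex `"female"` or `"male"`.
#' @return A one-row tibble.
#' @export
reference_profile <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  tibble::tibble(sex = sex, age = 55, sbp = 120, dbp = 80,
                 bp_treatment = 0, daily_smoker = 0, diabetes = 0, waist = 80)
}

# Centered predictor values in model units: u_p = (x_p - center_p) / scale_p.
# Returns an n x 7 matrix with columns in cvd_predictors order.
model_units <- function(profiles) {
  u <- vapply(cvd_predictors, function(p) {
    (as.numeric(profiles[[p]]) - predictor_centers[[p]]) / predictor_scales[[p]]
  }, numeric(nrow(profiles)))
  if (nrow(profiles) == 1L) u <- matrix(u, nrow = 1,
                                        dimnames = list(NULL, cvd_predictors))
  u
}

# Full design matrix for fitting: 7 main-effect columns in model units plus
# the 6 age-by-predictor interaction columns (u_age * u_p, p != age).
cox_design_matrix <- function(profiles, interactions = TRUE) {
  u <- model_units(profiles)
  if (!interactions) return(u)
  others <- setdiff(cvd_predictors, "age")
  inter <- u[, others, drop = FALSE] * u[, "age"]
  colnames(inter) <- paste0("age:", others)
  cbind(u, inter)
}
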