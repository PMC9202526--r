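#' Model outcomes and predictors
#'
#' The three cause-specific outcomes and the seven predictors used by every
#' submodel. Continuous predictors enter the linear predictor centered and
#' scaled to model units: age per 5 years (centered at 55), systolic and
#' diastolic blood pressure per 10 mm Hg (centered at 120 and 80), waist
#' circumference per 10 cm (centered at 80). Binary predictors are coded 0/1
#' and centered at 0 (absent).
#'
#' @name model-structure
#' @keywords internal
NULL

cvd_outcomes <- c("IHD", "IS", "HS")

cvd_predictors <- c("age", "sbp", "dbp", "bp_treatment", "daily_smoker",
                    "diabetes", "waist")

predictor_centers <- c(age = 55, sbp = 120, dbp = 80, bp_treatment = 0,
                       daily_smoker = 0, diabetes = 0, waist = 80)

predictor_scales <- c(age = 5, sbp = 10, dbp = 10, bp_treatment = 1,
                      daily_smoker = 1, diabetes = 1, waist = 10)

predictor_units <- c(age = "per 5 years", sbp = "per 10 mm Hg",
                     dbp = "per 10 mm Hg", bp_treatment = "yes vs no",
                     daily_smoker = "yes vs no", diabetes = "yes vs no",
                     waist = "per 10 cm")

#' Construct a coefficient set for one cause-specific submodel
#'
#' A coefficient set holds, for one sex and one outcome (ischemic heart
#' disease `"IHD"`, ischemic stroke `"IS"`, or hemorrhagic stroke `"HS"`),
#' the log-hazard-ratios of the seven predictors, the age-interaction
#' log-hazard-ratios (the change in each predictor's log-hazard-ratio per
#' 5 years of age), and the 10-year baseline survival `s0_10` of the
#' reference individual with all centered predictors at zero.
#'
#' @param outcome One of `"IHD"`, `"IS"`, `"HS"`.
#' @param sex One of `"female"`, `"male"`.
#' @param hr_main Named numeric vector of hazard ratios per model unit, one
#'   per predictor (names `age`, `sbp`, `dbp`, `bp_treatment`,
#'   `daily_smoker`, `diabetes`, `waist`).
#' @param hr_age_interaction Named numeric vector of age-interaction hazard
#'   ratios for every predictor except age.
#' @param s0_10 Baseline survival probability at 10 years, in (0, 1).
#'
#' @return An object of class `cvd_coef_set`: a list with elements
#'   `outcome`, `sex`, `terms` (a tibble with one row per predictor) and
#'   `s0_10`.
#' @export
#' @examples
#' coef_set(
#'   "IHD", "female",
#'   hr_main = c(age = 1.40, sbp = 1.02, dbp = 1.05, bp_treatment = 1.55,
#'               daily_smoker = 1.17, diabetes = 1.59, waist = 1.16),
#'   hr_age_interaction = c(sbp = 1.00, dbp = 0.99, bp_treatment = 0.95,
#'                          daily_smoker = 0.97, diabetes = 0.94,
#'                          waist = 0.97),
#'   s0_10 = 0.900
#' )
coef_set <- function(outcome, sex, hr_main, hr_age_interaction, s0_10) {
  outcome <- match.arg(outcome, cvd_outcomes)
  sex <- match.arg(sex, c("female", "male"))
  if (!is.numeric(s0_10) || length(s0_10) != 1L || s0_10 <= 0 || s0_10 >= 1) {
    abort("`s0_10` must be a single probability strictly inside (0, 1).")
  }
  missing_main <- setdiff(cvd_predictors, names(hr_main))
  if (length(missing_main)) {
    abort(paste0("`hr_main` is missing predictors: ",
                 paste(missing_main, collapse = ", ")))
  }
  extra_int <- setdiff(names(hr_age_interaction), setdiff(cvd_predictors, "age"))
  if (length(extra_int)) {
    abort(paste0("`hr_age_interaction` has unknown or disallowed entries: ",
                 paste(extra_int, collapse = ", ")))
  }
  hr_int_full <- setNames(rep(NA_real_, length(cvd_predictors)), cvd_predictors)
  hr_int_full[names(hr_age_interaction)] <- hr_age_interaction
  hr_main_full <- unname(hr_main[cvd_predictors])

  terms <- tibble::tibble(
    predictor = cvd_predictors,
    unit = unname(predictor_units[cvd_predictors]),
    center = unname(predictor_centers[cvd_predictors]),
    scale = unname(predictor_scales[cvd_predictors]),
    hr_main = hr_main_full,
    beta_main = log(hr_main_full),
    hr_age_interaction = unname(hr_int_full),
    beta_age_interaction = log(unname(hr_int_full))
  )
  structure(
    list(outcome = outcome, sex = sex, terms = terms, s0_10 = s0_10),
    class = "cvd_coef_set"
  )
}

#' @export
print.cvd_coef_set <- function(x, ...) {
  cat(sprintf("<cvd_coef_set> %s, %s; S0(10) = %.3f\n", x$outcome, x$sex,
              x$s0_10))
  print(x$terms, ...)
  invisible(x)
}

#' Assemble a model family from three cause-specific coefficient sets
#'
#' @param ihd,is,hs Coefficient sets (see [coef_set()]) for ischemic heart
#'   disease, ischemic stroke, and hemorrhagic stroke. All must share a sex.
#' @param metadata Optional list with `version` and `provenance` strings.
#'
#' @return An object of class `cvd_model_family`: the three submodels, the
#'   shared sex, metadata, and (after recalibration) per-region baseline
#'   survival overrides.
#' @export
model_family <- function(ihd, is, hs, metadata = list()) {
  sets <- list(IHD = ihd, IS = is, HS = hs)
  for (k in names(sets)) {
    if (!inherits(sets[[k]], "cvd_coef_set")) {
      abort(sprintf("Submodel `%s` is not a cvd_coef_set.", tolower(k)))
    }
    if (sets[[k]]$outcome != k) {
      abort(sprintf("Submodel passed as `%s` has outcome %s.",
                    tolower(k), sets[[k]]$outcome))
    }
  }
  sexes <- unique(vapply(sets, `[[`, "", "sex"))
  if (length(sexes) != 1L) {
    abort("All three coefficient sets must share one sex.")
  }
  metadata <- modifyList(list(version = "0.1.0", provenance = "unspecified"),
                         metadata)
  structure(
    list(sex = sexes, submodels = sets, metadata = metadata,
         s0_overrides = NULL, recalibration = NULL),
    class = "cvd_model_family"
  )
}

#' @export
print.cvd_model_family <- function(x, ...) {
  cat(sprintf("<cvd_model_family> sex = %s (version %s)\n", x$sex,
              x$metadata$version))
  s0 <- vapply(x$submodels, `[[`, 0, "s0_10")
  cat(sprintf("  S0(10): IHD %.3f, IS %.3f, HS %.3f\n",
              s0[["IHD"]], s0[["IS"]], s0[["HS"]]))
  if (!is.null(x$s0_overrides)) {
    cat(sprintf("  recalibrated (%s) for %d region(s)\n",
                x$recalibration$method,
                length(unique(x$s0_overrides$region))))
  }
  invisible(x)
}

#' Load a packaged published model family
#'
#' Returns the published sex-specific model: three cause-specific Cox
#' submodels whose hazard ratios, age-interaction hazard ratios, and pooled
#' 10-year baseline survivals were transcribed from the published model
#' tables (log-hazard-ratios are logs of the printed 2-decimal hazard
#' ratios).
#'
#' @param sex `"female"` or `"male"`.
#' @return A [model_family()] object.
#' @export
#' @examples
#' fam <- cvd_model("female")
#' fam$submodels$IHD$s0_10  # 0.900
cvd_model <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  path <- system.file("extdata", "models",
                      paste0("cvd_model_", sex, ".json"),
                      package = "cvdrisk", mustWork = TRUE)
  read_model_family(path)
}

#' Write and read model families as JSON
#'
#' The JSON schema stores, per submodel, the baseline survival and one
#' record per predictor holding both the hazard ratio (for human audit) and
#' the log-hazard-ratio actually used in prediction. Recalibration
#' overrides, when present, are stored in a `region_overrides` block.
#'
#' @param family A `cvd_model_family`.
#' @param path File path.
#' @return `write_model_family()` returns `path` invisibly;
#'   `read_model_family()` returns a `cvd_model_family`.
#' @export
write_model_family <- function(family, path) {
  stopifnot(inherits(family, "cvd_model_family"))
  # decimal JSON numbers lose the last bit; hex-float companions keep the
  # prediction-critical values exact across the round trip
  hexf <- function(x) ifelse(is.na(x), NA_character_, sprintf("%a", x))
  payload <- list(
    schema_version = "1.0",
    sex = family$sex,
    metadata = family$metadata,
    submodels = lapply(family$submodels, function(cs) {
      terms <- as.data.frame(cs$terms)
      terms$beta_main_hex <- hexf(terms$beta_main)
      terms$beta_age_interaction_hex <- hexf(terms$beta_age_interaction)
      list(outcome = cs$outcome, s0_10 = cs$s0_10,
           s0_10_hex = hexf(cs$s0_10), terms = terms)
    })
  )
  if (!is.null(family$s0_overrides)) {
    payload$recalibration <- list(
      method = family$recalibration$method,
      correction_factors = as.data.frame(family$recalibration$factors)
    )
    ov <- as.data.frame(family$s0_overrides)
    ov$s0_10_hex <- hexf(ov$s0_10)
    payload$region_overrides <- ov
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_model_family
#' @export
read_model_family <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  unhex <- function(hex, dec) {
    if (is.null(hex)) return(dec)
    ifelse(is.na(hex), NA_real_, suppressWarnings(as.numeric(hex)))
  }
  sets <- lapply(payload$submodels, function(sm) {
    terms <- tibble::as_tibble(sm$terms)
    hr_main <- setNames(terms$hr_main, terms$predictor)
    hr_int <- setNames(terms$hr_age_interaction, terms$predictor)
    hr_int <- hr_int[!is.na(hr_int)]
    cs <- coef_set(sm$outcome, payload$sex, hr_main, hr_int,
                   unhex(sm$s0_10_hex, sm$s0_10))
    # restore the stored log-HRs verbatim (exact hex floats when present):
    # they, not the display HRs, are the prediction-critical quantities
    ord <- match(cs$terms$predictor, terms$predictor)
    cs$terms$beta_main <-
      unhex(terms$beta_main_hex, terms$beta_main)[ord]
    cs$terms$beta_age_interaction <-
      unhex(terms$beta_age_interaction_hex, terms$beta_age_interaction)[ord]
    cs
  })
  if (!is.null(payload$region_overrides$s0_10_hex)) {
    payload$region_overrides$s0_10 <-
      unhex(payload$region_overrides$s0_10_hex, payload$region_overrides$s0_10)
    payload$region_overrides$s0_10_hex <- NULL
  }
  fam <- model_family(sets$IHD, sets$IS, sets$HS,
                      metadata = payload$metadata)
  if (!is.null(payload$region_overrides)) {
    fam$s0_overrides <- tibble::as_tibble(payload$region_overrides)
    fam$recalibration <- list(
      method = payload$recalibration$method,
      factors = tibble::as_tibble(payload$recalibration$correction_factors)
    )
  }
  fam
}

# Submodel lookup with a clear error when a family is incomplete.
get_submodel <- function(family, outcome) {
  outcome <- match.arg(outcome, cvd_outcomes)
  cs <- family$submodels[[outcome]]
  if (is.null(cs)) {
    abort(sprintf("Model family has no %s submodel.", outcome))
  }
  cs
}

# Baseline survival for one outcome, honouring region overrides when the
# family has been recalibrated and a region is supplied.
s0_for <- function(family, outcome, region = NULL) {
  cs <- get_submodel(family, outcome)
  if (is.null(region) || is.null(family$s0_overrides)) {
    return(rep(cs$s0_10, length(region %||% 1L)))
  }
  ov <- family$s0_overrides[family$s0_overrides$outcome == outcome, ]
  idx <- match(as.character(region), as.character(ov$region))
  s0 <- ov$s0_10[idx]
  s0[is.na(idx)] <- cs$s0_10
  s0
}
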