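#' Configuration for the synthetic multi-region cohort generator
#'
#' The generator emulates the structure of a large 10-region Chinese
#' cohort: covariates drawn around the published baseline summaries, three
#' cause-specific event processes whose hazards are
#' \eqn{\lambda_k = \lambda_{0k,region} \exp(LP_k)} with the linear
#' predictors of the true coefficient sets, region-varying baseline
#' hazards, administrative censoring at 10-13 years, and a small random
#' loss to follow-up.
#'
#' Defaults (per sex, female/male): daily smoking prevalence 0.020/0.571;
#' blood-pressure-lowering treatment 0.118/0.102; self-reported diabetes
#' 0.029/0.025; SBP mean 126/129.5 and DBP mean 76/78.5 mm Hg (SDs 20/11,
#' correlation 0.7); waist mean 78.2/81.3 cm (SD 9.6/10.4); age uniform on
#' 30-79. Outcome-level baseline hazards are chosen so that multiplier-1
#' regions reproduce the published 10-year baseline survivals
#' (\eqn{\lambda_{0k} = -\ln s_{0k}(10)/10}); per-region multipliers span
#' [0.5, 2] on a geometric grid, rotated across outcomes so that regions
#' differ in their outcome mix.
#'
#' @param n_per_region Subjects per region.
#' @param n_regions Number of regions.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @param sex `"female"`, `"male"`, or `"both"` (then `sex_mix` applies).
#' @param sex_mix Probability that a subject is female when `sex = "both"`.
#' @param families Named list of true [model_family()] objects (`female`,
#'   `male`); defaults to the packaged published models.
#' @param hazard_multipliers Optional `n_regions x 3` matrix (columns IHD,
#'   IS, HS) of per-region baseline-hazard multipliers; default geometric
#'   grid on [0.5, 2], rotated per outcome.
#' @param death_rate Constant competing hazard of non-CVD death (per
#'   person-year).
#' @param unspecified_fraction Hazard of unspecified stroke as a fraction
#'   of the combined stroke hazard.
#' @param admin_window Administrative censoring window in years,
#'   `c(min, max)`; each subject's censoring time is uniform on it.
#' @param loss_fraction Fraction of subjects lost to follow-up at a
#'   uniform random time before their administrative censoring (< 0.05).
#' @param weibull_shape Shape of the event-time process (1 = exponential,
#'   the default; other values give Weibull hazards sharing the shape
#'   across causes, for robustness checks).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_region = 20000, n_regions = 10, seed,
                       sex = c("female", "male", "both"), sex_mix = 0.59,
                       families = NULL, hazard_multipliers = NULL,
                       death_rate = 0.005, unspecified_fraction = 0.013,
                       admin_window = c(10, 13), loss_fraction = 0.008,
                       weibull_shape = 1) {
  if (missing(seed)) abort("`seed` is mandatory in a sim_config.")
  sex <- match.arg(sex)
  if (loss_fraction < 0 || loss_fraction >= 0.05) {
    abort("`loss_fraction` must be in [0, 0.05).")
  }
  if (sex_mix < 0 || sex_mix > 1) abort("`sex_mix` must be in [0, 1].")
  families <- families %||% list(female = cvd_model("female"),
                                 male = cvd_model("male"))
  if (is.null(hazard_multipliers)) {
    grid <- if (n_regions == 1L) 1 else
      0.5 * 4^((seq_len(n_regions) - 1) / (n_regions - 1))
    shift <- floor(n_regions / 3)
    hazard_multipliers <- cbind(
      IHD = grid,
      IS = grid[((seq_len(n_regions) - 1 + shift) %% n_regions) + 1],
      HS = grid[((seq_len(n_regions) - 1 + 2 * shift) %% n_regions) + 1]
    )
  }
  hazard_multipliers <- as.matrix(hazard_multipliers)
  if (nrow(hazard_multipliers) != n_regions ||
      ncol(hazard_multipliers) != 3L) {
    abort("`hazard_multipliers` must be an n_regions x 3 matrix (IHD, IS, HS).")
  }
  if (any(hazard_multipliers <= 0)) abort("Hazard multipliers must be > 0.")
  colnames(hazard_multipliers) <- cvd_outcomes
  if (admin_window[1] > admin_window[2] || admin_window[1] <= 0) {
    abort("`admin_window` must be 0 < min <= max.")
  }
  structure(
    list(n_per_region = n_per_region, n_regions = n_regions,
         seed = as.integer(seed), sex = sex, sex_mix = sex_mix,
         families = families, hazard_multipliers = hazard_multipliers,
         death_rate = death_rate,
         unspecified_fraction = unspecified_fraction,
         admin_window = admin_window, loss_fraction = loss_fraction,
         weibull_shape = weibull_shape),
    class = "sim_config"
  )
}

# Covariate location/scale defaults per sex (around the published baseline
# medians; SDs from the printed interquartile ranges, blood-pressure SDs
# and correlation are declared generator defaults).
covariate_defaults <- list(
  female = list(sbp_mean = 126.0, dbp_mean = 76.0, sbp_sd = 20, dbp_sd = 11,
                bp_cor = 0.7, waist_mean = 78.2, waist_sd = 9.6,
                p_smoker = 0.020, p_treatment = 0.118, p_diabetes = 0.029),
  male = list(sbp_mean = 129.5, dbp_mean = 78.5, sbp_sd = 20, dbp_sd = 11,
              bp_cor = 0.7, waist_mean = 81.3, waist_sd = 10.4,
              p_smoker = 0.571, p_treatment = 0.102, p_diabetes = 0.025)
)

draw_profiles <- function(n, sex) {
  d <- covariate_defaults[[sex]]
  age <- runif(n, 30, 79)
  z1 <- rnorm(n)
  z2 <- d$bp_cor * z1 + sqrt(1 - d$bp_cor^2) * rnorm(n)
  sbp <- pmin(pmax(d$sbp_mean + d$sbp_sd * z1, 60), 280)
  dbp <- pmin(pmax(d$dbp_mean + d$dbp_sd * z2, 30), 200)
  dbp <- pmin(dbp, sbp)                       # physiological constraint
  waist <- pmin(pmax(rnorm(n, d$waist_mean, d$waist_sd), 40), 180)
  tibble::tibble(
    sex = sex, age = age, sbp = sbp, dbp = dbp,
    bp_treatment = rbinom(n, 1, d$p_treatment),
    daily_smoker = rbinom(n, 1, d$p_smoker),
    diabetes = rbinom(n, 1, d$p_diabetes),
    waist = waist
  )
}

#' Simulate a multi-region cohort
#'
#' Draws covariates, assigns each subject cause-specific event hazards
#' from the true coefficient sets and region multipliers, generates the
#' first-event time across causes (IHD, IS, HS, unspecified stroke,
#' non-CVD death), and censors at the administrative window or at random
#' loss to follow-up. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A cohort tibble (see [validate_cohort()]).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_region = 100, n_regions = 2,
#'                                      seed = 42))
#' table(cohort$event)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- config$n_per_region * config$n_regions
  region <- rep(as.character(seq_len(config$n_regions)),
                each = config$n_per_region)

  sexes <- switch(config$sex,
                  female = rep("female", n),
                  male = rep("male", n),
                  both = ifelse(runif(n) < config$sex_mix, "female", "male"))
  prof <- dplyr::bind_rows(lapply(c("female", "male"), function(s) {
    ix <- which(sexes == s)
    if (!length(ix)) return(NULL)
    dplyr::mutate(draw_profiles(length(ix), s), .row = ix)
  }))
  prof <- dplyr::arrange(prof, .data$.row)
  prof$.row <- NULL

  # Cause-specific hazards lambda_k = lambda0_k * mult[region, k] * exp(LP_k),
  # with lambda0_k = -ln(s0_k(10)) / 10 so multiplier-1 regions reproduce
  # the published baseline survivals.
  lam <- matrix(0, n, 3, dimnames = list(NULL, cvd_outcomes))
  for (s in c("female", "male")) {
    ix <- which(prof$sex == s)
    if (!length(ix)) next
    fam <- config$families[[s]]
    for (k in cvd_outcomes) {
      cs <- get_submodel(fam, k)
      lam0 <- -log(cs$s0_10) / 10
      mult <- config$hazard_multipliers[as.integer(region[ix]), k]
      lam[ix, k] <- lam0 * mult * exp(linear_predictor(prof[ix, ], cs))
    }
  }
  lam_us <- config$unspecified_fraction * (lam[, "IS"] + lam[, "HS"])
  lam_death <- rep(config$death_rate, n)
  lam_all <- cbind(lam, unspecified_stroke = lam_us, death_other = lam_death)
  total <- rowSums(lam_all)

  p10 <- 1 - exp(-(total * 10^config$weibull_shape))
  if (any(p10 > 0.99)) {
    warn(sprintf("%d subject(s) have > 99%% 10-year event probability; check hazards.",
                 sum(p10 > 0.99)))
  }

  # First event time: total cumulative hazard total * t^shape; cause drawn
  # proportionally to the (time-constant) cause hazard ratios.
  e <- rexp(n)
  t_event <- ifelse(total > 0, (e / total)^(1 / config$weibull_shape), Inf)
  cause_u <- runif(n)
  cum <- lam_all / ifelse(total > 0, total, 1)
  for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + cum[, j]
  cause_idx <- 1L + rowSums(cause_u > cum)
  cause <- colnames(lam_all)[pmin(cause_idx, ncol(lam_all))]

  t_admin <- runif(n, config$admin_window[1], config$admin_window[2])
  lost <- runif(n) < config$loss_fraction
  t_loss <- ifelse(lost, runif(n) * t_admin, Inf)
  t_cens <- pmin(t_admin, t_loss)

  time <- pmin(t_event, t_cens)
  event <- ifelse(t_event <= t_cens, cause, "none")

  dplyr::bind_cols(
    tibble::tibble(id = sprintf("S%07d", seq_len(n)), region = region),
    prof,
    tibble::tibble(time = time, event = event)
  )
}

#' Cross-sectional recalibration summaries from a cohort
#'
#' Tabulates, per region x sex x 5-year age band, the band's population
#' share, the mean of each predictor, and the annual incidence of each
#' outcome (first events by the horizon divided by person-years at risk up
#' to the horizon) - the summary table the practical recalibration method
#' consumes.
#'
#' @param cohort A cohort table.
#' @param horizon Horizon in years for the incidence tabulation.
#' @return A [validate_recalibration_table()]-conformant tibble.
#' @export
make_recalibration_table <- function(cohort, horizon = 10) {
  cohort <- validate_cohort(cohort)
  bands <- seq(30, 80, by = 5)
  cohort$age_group <- cut(cohort$age, breaks = bands, right = FALSE,
                          labels = sprintf("%d-%d", bands[-length(bands)],
                                           bands[-1] - 1))
  py <- pmin(cohort$time, horizon)
  out <- cohort |>
    dplyr::mutate(py = py) |>
    dplyr::group_by(.data$region, .data$sex, .data$age_group, .drop = TRUE) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(cvd_predictors), mean),
      person_years = sum(.data$py),
      incidence_ihd = sum(.data$event == "IHD" & .data$time <= horizon) /
        sum(.data$py),
      incidence_is = sum(.data$event == "IS" & .data$time <= horizon) /
        sum(.data$py),
      incidence_hs = sum(.data$event == "HS" & .data$time <= horizon) /
        sum(.data$py),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(population_share = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(age_group = as.character(.data$age_group))
  n_bands <- dplyr::count(out, .data$region, .data$sex)
  if (any(n_bands$n < length(bands) - 1L)) {
    warn("Some region x sex strata have empty 5-year age bands; those bands were dropped.")
  }
  validate_recalibration_table(out)
}
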