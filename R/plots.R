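#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Calibration plot
#'
#' Mean predicted versus Kaplan-Meier observed 10-year risk per decile of
#' predicted risk, with observed-risk confidence bars and the identity
#' line of perfect calibration.
#'
#' @param object A `cvd_calibration` table from [calibration_table()] or
#'   an evaluation's `$calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cvd_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$obs.low,
                                        ymax = .data$obs.high),
                           width = 0, colour = "grey30") +
    ggplot2::geom_point(size = 2, colour = "#2166ac") +
    ggplot2::labs(
      x = sprintf("Mean predicted %g-year risk", attr(object, "horizon") %||% 10),
      y = sprintf("Observed %g-year risk (Kaplan-Meier)",
                  attr(object, "horizon") %||% 10)
    ) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of fitted hazard ratios
#'
#' @param object A `cvd_cox_fit`.
#' @param ... Unused.
#' @return A ggplot of hazard ratios with 95% CIs on a log scale.
#' @export
autoplot.cvd_cox_fit <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_point(size = 2, colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL,
                  title = sprintf("%s submodel (%s)", object$outcome, object$sex)) +
    ggplot2::theme_minimal()
}
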