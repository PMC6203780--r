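#' Calibration plot: observed vs mean predicted risk by tenths
#'
#' @param object A [calibration_by_tenths()] result.
#' @param ... Unused.
#' @return A ggplot object (identity line = perfect calibration).
#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(
      x = "Mean predicted probability",
      y = "Observed probability (Kaplan–Meier)",
      title = sprintf("Calibration by tenths of predicted risk (%g-year horizon)",
                      attr(object, "horizon") %||% NA)
    ) +
    ggplot2::theme_minimal()
}

#' Relative-risk calibration curve plot
#'
#' @param object An [rr_calibration()] result.
#' @param ... Unused.
#' @return A ggplot object on log-HR axes; the dashed identity line is
#'   perfect relative-risk calibration.
#' @method autoplot rr_calibration
#' @export
autoplot.rr_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pred_hr, y = .data$est_hr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Model-predicted hazard ratio",
                  y = "Estimated hazard ratio",
                  title = "Relative-risk calibration") +
    ggplot2::theme_minimal()
}

#' Change-in-risk scatter plot
#'
#' Initial (base-model) predicted risk against the change in predicted risk
#' after adding the GRS; points hugging the horizontal zero line mean the
#' GRS leaves most predictions essentially unchanged.
#'
#' @param object A [delta_risk_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_risk_summary
#' @export
autoplot.delta_risk_summary <- function(object, ...) {
  detail <- attr(object, "detail")
  thr <- object$threshold[1]
  ggplot2::ggplot(detail, ggplot2::aes(x = .data$risk_base, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::labs(x = "Predicted probability, base model",
                  y = "Change in predicted probability after adding the GRS",
                  title = "Change in 5-year predicted risk") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
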