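#' Observed-versus-predicted diagnostic plot
#'
#' Observed concentrations against population (PRED) and individual
#' (IPRED) predictions on log-log axes, faceted by matrix, with the line
#' of identity.
#'
#' @param object An `flx_fit`.
#' @param data Dataset to plot (default the fitted data); BLQ records are
#'   dropped.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flx_fit
#' @export
autoplot.flx_fit <- function(object, data = NULL, ...) {
  d <- pred_ipred(object, data)
  d <- dplyr::filter(d, !.data$blq, .data$conc_ng_per_ml > 0)
  long <- tidyr::pivot_longer(d, c("pred", "ipred"),
                              names_to = "prediction", values_to = "value")
  long$prediction <- toupper(long$prediction)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     y = .data$conc_ng_per_ml)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(matrix ~ prediction, scales = "free") +
    ggplot2::labs(x = "Predicted concentration (ng/mL)",
                  y = "Observed concentration (ng/mL)")
}

#' Visual-predictive-check plot
#'
#' Observed percentile bands overlaid on the simulation envelopes from
#' [vpc_percentiles()], faceted by matrix.
#'
#' @param vpc Output of [vpc_percentiles()].
#' @return A ggplot object.
#' @export
plot_vpc <- function(vpc) {
  vpc$level_lab <- paste0("P", 100 * vpc$level)
  ggplot2::ggplot(vpc, ggplot2::aes(x = .data$time_h, group = .data$level_lab)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo, ymax = .data$sim_hi,
                                      fill = .data$level_lab), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_med,
                                    colour = .data$level_lab), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$level_lab)) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~matrix, scales = "free") +
    ggplot2::labs(x = "Time since first dose (h)",
                  y = "Concentration (ng/mL)",
                  colour = "Percentile", fill = "Percentile")
}

#' Detection-time quantile plot
#'
#' Detection-time quantiles per regimen and matrix from
#' [detection_quantiles()].
#'
#' @param object An `flx_dtq`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flx_dtq
#' @export
autoplot.flx_dtq <- function(object, ...) {
  d <- tidy(object)
  d$limit_lab <- paste0(d$matrix, " ≥ ", d$limit_ng_per_ml, " ng/mL")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$dt_h,
                                  colour = .data$regimen)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~limit_lab, scales = "free_y") +
    ggplot2::labs(x = "Population quantile (%)",
                  y = "Detection time after last dose (h)",
                  colour = "Regimen")
}
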