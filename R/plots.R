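# ggplot2 displays for the main result types.

#' Plot a pulse trace
#'
#' @param object A `pulse_trace`.
#' @param ... Unused.
#' @return A ggplot (power in kW vs time in fs).
#' @export
autoplot.pulse_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time * 1e15,
                                       y = .data$power / 1e3)) +
    ggplot2::geom_line(color = "#B2182B") +
    ggplot2::labs(x = "Time (fs)", y = "Power (kW)",
                  title = attr(object, "label") %||% NULL) +
    ggplot2::theme_minimal()
}

#' Plot an intensity autocorrelation
#'
#' @param object An `acf_trace`.
#' @param ... Unused.
#' @return A ggplot with the half-max level marked.
#' @export
autoplot.acf_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag * 1e15, y = .data$value)) +
    ggplot2::geom_line(color = "#2166AC") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "Lag (fs)", y = "Normalized ACF") +
    ggplot2::theme_minimal()
}

#' Plot per-laser efficiency with dispersion
#'
#' @param object An `eta_study`.
#' @param ... Unused.
#' @return A ggplot of eta (mean +/- SD) per laser, with the reference
#'   level eta = 1 marked.
#' @export
autoplot.eta_study <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$laser, y = .data$eta_mean)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$eta_mean - .data$eta_sd,
      ymax = .data$eta_mean + .data$eta_sd)) +
    ggplot2::labs(x = NULL, y = expression(eta ~ "(2p excitation efficiency)")) +
    ggplot2::theme_minimal()
}

#' Log-log power series by laser
#'
#' @param points Per-point tibble with `power`, `fluorescence`,
#'   `laser_label` (e.g. `eta_study()$points`).
#' @return A ggplot on log10-log10 axes; the 2p power law appears as a
#'   straight line of slope 2.
#' @export
plot_power_series <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(x = .data$power * 1e3,
                                       y = .data$fluorescence,
                                       color = .data$laser_label)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Average power (mW)", y = "Fluorescence (norm. counts/ms)",
                  color = "Laser") +
    ggplot2::theme_minimal()
}
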