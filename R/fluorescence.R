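# Relative two-photon fluorescence prediction.
#
# 2p excited fluorescence is proportional to the time average of the
# squared instantaneous power: F = R * integral(Ppulse(t)^2 dt) up to a
# constant that depends on the fluorophore and collection optics. All
# predictions here are therefore relative; only ratios are meaningful.

#' Predict relative 2p fluorescence from a pulse trace
#'
#' The trace (which may be in arbitrary amplitude units, e.g. a FROG
#' reconstruction normalized to peak 1) is rescaled so that its
#' trapezoidal integral equals the single-pulse energy at the assumed
#' average power (`avg_power / rep_rate`); the prediction is then
#' `rep_rate * integral(power^2 dt)`. The result is independent of the
#' input trace's amplitude units and scales with `avg_power^2`.
#'
#' @param trace A pulse trace (arbitrary power units allowed).
#' @param rep_rate Repetition rate, Hz.
#' @param avg_power Assumed average power, watts (default 1 W).
#' @param label Label for the prediction row.
#' @return A one-row tibble with columns `value` (W^2, relative),
#'   `rep_rate`, `avg_power`, `label`.
#' @examples
#' tr <- generate_pulse(pulse_spec("sech2", 100e-15, energy = 12.5e-9))
#' predict_fluorescence(tr, 80e6)$value
#' @export
predict_fluorescence <- function(trace, rep_rate, avg_power = 1,
                                 label = attr(trace, "label") %||% "") {
  validate_pulse_trace(trace)
  abort_if(rep_rate <= 0, "`rep_rate` must be positive.")
  abort_if(avg_power <= 0, "`avg_power` must be positive.")
  raw_energy <- trapz(trace$time, trace$power)
  abort_if(raw_energy <= 0, "Trace has zero integral; cannot power-normalize.")
  p <- trace$power * (avg_power / rep_rate) / raw_energy
  tibble::tibble(
    value = rep_rate * trapz(trace$time, p^2),
    rep_rate = rep_rate,
    avg_power = avg_power,
    label = label
  )
}

#' Ideal relative fluorescence from scalar laser parameters
#'
#' The square-pulse scaling law F = Pav^2 / (R * tau_p), with the
#' proportionality constant fixed to 1: only ratios between lasers are
#' meaningful.
#'
#' @param avg_power Average power, watts.
#' @param rep_rate Repetition rate, Hz.
#' @param pulse_duration Pulse FWHM, seconds.
#' @return Dimensionless relative fluorescence.
#' @examples
#' ideal_fluorescence(1, 80e6, 100e-15) / ideal_fluorescence(1, 80e6, 125e-15) # 1.25
#' @export
ideal_fluorescence <- function(avg_power, rep_rate, pulse_duration) {
  abort_if(any(avg_power <= 0) || any(rep_rate <= 0) || any(pulse_duration <= 0),
           "All arguments must be positive.")
  avg_power^2 / (rep_rate * pulse_duration)
}

#' FROG-predicted fluorescence ratio between two lasers
#'
#' Ratio of trace-based fluorescence predictions for a test laser over a
#' reference laser, each computed at the same assumed average power
#' (1 W by default; the ratio is independent of the choice).
#'
#' @param test_trace,ref_trace Pulse traces (arbitrary amplitude units).
#' @param test_rate,ref_rate Repetition rates, Hz.
#' @param avg_power Assumed common average power, watts.
#' @return Dimensionless ratio F_test / F_ref.
#' @export
frog_predicted_ratio <- function(test_trace, test_rate, ref_trace, ref_rate,
                                 avg_power = 1) {
  predict_fluorescence(test_trace, test_rate, avg_power)$value /
    predict_fluorescence(ref_trace, ref_rate, avg_power)$value
}
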