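# Intensity autocorrelation of pulse traces.
#
# The intensity autocorrelation function (ACF) A(tau) = integral of
# P(t) P(t + tau) dt is what an autocorrelator measures; it is symmetric
# for any pulse profile and is peak-normalized to 1 here. The width of
# the ACF at half its amplitude ("autocorrelation time") divided by a
# shape-specific deconvolution factor gives the reported pulse duration.

#' Deconvolution factors from ACF width to pulse FWHM
#'
#' The factor for a sech-squared pulse is quoted as 1.54 throughout the
#' ultrafast literature (the exact numeric value is 1.5427); Gaussian
#' autoconvolution widens by sqrt(2); a square pulse's triangular ACF has
#' the same half-max width as the pulse itself.
#' @format Named numeric vector.
#' @export
DECONVOLUTION_FACTORS <- c(sech2 = 1.54, gaussian = sqrt(2), square = 1)

#' Intensity autocorrelation of a pulse trace
#'
#' Computes A(tau) on the trace's own grid (lags spanning the trace's
#' time span), normalized so A(0) = 1. Values outside overlapping
#' support are zero. The discrete correlation is evaluated with an FFT
#' (`stats::convolve`), converted to trapezoidal weighting over the
#' overlap region, and mirrored onto negative lags, so the result is
#' symmetric by construction and matches a direct shift-multiply-
#' trapezoid evaluation to round-off.
#'
#' @param trace A pulse trace (see [generate_pulse()]).
#' @return An `acf_trace` tibble with columns `lag` (s, symmetric about
#'   0) and `value` (dimensionless, max 1).
#' @examples
#' tr <- generate_pulse(pulse_spec("sech2", 100e-15, energy = 12.5e-9))
#' acf_width(intensity_acf(tr)) # about 154 fs
#' @export
intensity_acf <- function(trace) {
  validate_pulse_trace(trace)
  p <- trace$power
  abort_if(trapz(trace$time, p) <= 0,
           "Zero-energy trace: ACF normalization undefined.")
  n <- length(p)
  dt <- (trace$time[n] - trace$time[1L]) / (n - 1L)
  # full discrete cross-correlation of p with itself, lags -(n-1)..(n-1)
  raw <- stats::convolve(p, p, type = "open") * dt
  # convert the rectangle sums to trapezoidal sums over the overlap
  # region: subtract half the endpoint products at each lag
  k <- 0:(n - 1L)
  pos <- raw[n + k] - 0.5 * dt * (p[1L] * p[1L + k] + p[n - k] * p[n])
  sym <- c(rev(pos[-1L]), pos)
  lags <- seq.int(-(n - 1L), n - 1L) * dt
  vals <- sym / max(sym)
  vals[vals < 0] <- 0 # FFT round-off can leave tiny negatives in the tails
  out <- tibble::new_tibble(
    list(lag = lags, value = vals),
    nrow = length(lags),
    class = "acf_trace"
  )
  attr(out, "source_label") <- attr(trace, "label") %||% ""
  out
}

#' Autocorrelation time (full width of the ACF at half maximum)
#'
#' The full width between the two points where the ACF decays to half
#' its (unit) amplitude, linearly interpolated between samples.
#'
#' @param acf An `acf_trace` from [intensity_acf()].
#' @return Width in seconds.
#' @export
acf_width <- function(acf) {
  abort_if(!all(c("lag", "value") %in% names(acf)),
           "An ACF trace needs `lag` and `value` columns.")
  fwhm_of_profile(acf$lag, acf$value)
}

#' Deconvolve an ACF width into a pulse duration
#'
#' @param acf_width ACF half-max full width, seconds.
#' @param assumed_shape `"sech2"` (factor 1.54), `"gaussian"` (sqrt(2)),
#'   or `"square"` (1).
#' @return Pulse FWHM in seconds under the assumed shape.
#' @examples
#' deconvolve_duration(154e-15, "sech2") # 100 fs
#' @export
deconvolve_duration <- function(acf_width, assumed_shape = c("sech2", "gaussian", "square")) {
  assumed_shape <- match.arg(assumed_shape)
  abort_if(acf_width <= 0, "`acf_width` must be positive.")
  acf_width / DECONVOLUTION_FACTORS[[assumed_shape]]
}

#' @export
print.acf_trace <- function(x, ...) {
  cat(sprintf("<acf_trace: %d lags, half-max width %.4g fs>\n",
              nrow(x), acf_width(x) * 1e15))
  NextMethod()
}
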