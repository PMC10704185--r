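# Parametric femtosecond pulse profiles on a uniform time grid.
#
# A pulse trace is a tibble with columns `time` (seconds, strictly
# increasing uniform grid) and `power` (watts, >= 0), carrying the label
# in the "label" attribute. The grid is centered on the main peak and
# wide enough that the profile decays below 1e-6 of its maximum at both
# ends, so every pulse is fully contained.

# sech^2 FWHM relative to its natural width t0: P(t) = Ppk * sech^2(t/t0)
SECH2_FWHM_FACTOR <- 2 * acosh(sqrt(2)) # 1.7627...

DECAY_THRESHOLD <- 1e-6

#' Describe a pulse shape
#'
#' Builds the parametric description consumed by [generate_pulse()].
#' Exactly one of `energy` or `peak_power` fixes the overall scale.
#'
#' @param shape One of `"sech2"`, `"gaussian"`, `"square"`, `"composite"`.
#' @param fwhm Full width at half maximum of the (main) peak, seconds.
#' @param energy Pulse energy in joules, or `NULL`.
#' @param peak_power Peak power in watts, or `NULL`.
#' @param lobes For `"composite"` only: a data frame with columns `delay`
#'   (seconds), `relative_height` (in (0, 1], exactly one lobe at 1), and
#'   `fwhm` (seconds). Composite pulses are sums of sech-squared lobes.
#' @return A `pulse_spec` list.
#' @examples
#' pulse_spec("sech2", fwhm = 125e-15, energy = 12.5e-9)
#' @export
pulse_spec <- function(shape = c("sech2", "gaussian", "square", "composite"),
                       fwhm, energy = NULL, peak_power = NULL, lobes = NULL) {
  shape <- match.arg(shape)
  abort_if(!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0,
           "`fwhm` must be a single positive duration in seconds.")
  abort_if(is.null(energy) == is.null(peak_power),
           "Exactly one of `energy` or `peak_power` must be set.")
  if (!is.null(energy))
    abort_if(energy <= 0, "`energy` must be positive.")
  if (!is.null(peak_power))
    abort_if(peak_power <= 0, "`peak_power` must be positive.")
  if (shape == "composite") {
    abort_if(is.null(lobes) || nrow(lobes) < 1L,
             "Composite pulses need at least one lobe.")
    abort_if(!all(c("delay", "relative_height", "fwhm") %in% names(lobes)),
             "`lobes` needs columns delay, relative_height, fwhm.")
    abort_if(any(lobes$relative_height <= 0 | lobes$relative_height > 1),
             "Lobe relative heights must lie in (0, 1].")
    abort_if(sum(lobes$relative_height == 1) != 1L,
             "Exactly one lobe must have relative height 1 (the main peak).")
    abort_if(any(lobes$fwhm <= 0), "Lobe FWHMs must be positive.")
  } else {
    abort_if(!is.null(lobes), "`lobes` is only meaningful for composite pulses.")
  }
  structure(
    list(shape = shape, fwhm = fwhm, energy = energy,
         peak_power = peak_power, lobes = lobes),
    class = "pulse_spec"
  )
}

# unit-peak profile of one shape on a time grid
shape_profile <- function(shape, t, fwhm) {
  switch(
    shape,
    sech2 = {
      t0 <- fwhm / SECH2_FWHM_FACTOR
      1 / cosh(t / t0)^2
    },
    gaussian = exp(-4 * log(2) * (t / fwhm)^2),
    square = as.numeric(abs(t) <= fwhm / 2)
  )
}

#' Generate a pulse trace from a shape description
#'
#' Samples the pulse power profile on a uniform grid centered on the main
#' peak and rescales it so the trapezoidal integral matches the requested
#' energy (or the maximum matches the requested peak power).
#'
#' @param spec A [pulse_spec()].
#' @param grid_span Grid span as a multiple of the FWHM (>= 20; default 40).
#' @param n_samples Number of grid points (>= 4096; default 8192).
#' @param label Trace label.
#' @return A `pulse_trace` tibble with columns `time` (s) and `power` (W).
#' @examples
#' tr <- generate_pulse(pulse_spec("sech2", 125e-15, energy = 12.5e-9))
#' pulse_energy(tr)
#' @export
generate_pulse <- function(spec, grid_span = 40, n_samples = 8192,
                           label = spec$shape) {
  abort_if(!inherits(spec, "pulse_spec"), "`spec` must be a pulse_spec.")
  abort_if(grid_span < 20, "`grid_span` must be at least 20 FWHM.")
  abort_if(n_samples < 4096, "`n_samples` must be at least 4096.")
  half <- grid_span * spec$fwhm / 2
  t <- seq(-half, half, length.out = n_samples)
  if (spec$shape == "composite") {
    p <- rowSums(vapply(
      seq_len(nrow(spec$lobes)),
      function(i) {
        l <- spec$lobes[i, ]
        l$relative_height * shape_profile("sech2", t - l$delay, l$fwhm)
      },
      numeric(length(t))
    ))
  } else {
    p <- shape_profile(spec$shape, t, spec$fwhm)
  }
  mx <- max(p)
  if (spec$shape != "square") {
    abort_if(p[1L] > DECAY_THRESHOLD * mx || p[n_samples] > DECAY_THRESHOLD * mx,
             paste0("Grid span too small: pulse has not decayed below 1e-6 of ",
                    "its maximum at the grid ends. Increase `grid_span`."))
  }
  if (!is.null(spec$energy)) {
    p <- p * (spec$energy / trapz(t, p))
  } else {
    p <- p * (spec$peak_power / mx)
  }
  new_pulse_trace(t, p, label)
}

new_pulse_trace <- function(time, power, label = "") {
  out <- tibble::new_tibble(
    list(time = time, power = power),
    nrow = length(time),
    class = "pulse_trace"
  )
  attr(out, "label") <- label
  out
}

#' Validate a pulse trace
#'
#' Checks the uniform-grid, non-negativity, and full-containment
#' invariants that all pulse operations rely on.
#'
#' @param trace A data frame with numeric `time` and `power` columns.
#' @return The trace, invisibly, if valid; otherwise an error.
#' @export
validate_pulse_trace <- function(trace) {
  abort_if(!all(c("time", "power") %in% names(trace)),
           "A pulse trace needs `time` and `power` columns.")
  abort_if(nrow(trace) < 2L, "A pulse trace needs at least two samples.")
  abort_if(any(diff(trace$time) <= 0), "`time` must be strictly increasing.")
  abort_if(grid_jitter(trace$time) > 1e-9,
           "`time` must be a uniform grid (relative jitter above 1e-9).")
  abort_if(any(trace$power < 0), "`power` must be non-negative.")
  invisible(trace)
}

#' Pulse energy by trapezoidal integration
#'
#' @param trace A pulse trace (`time` in s, `power` in W).
#' @return Energy in joules.
#' @export
pulse_energy <- function(trace) {
  validate_pulse_trace(trace)
  trapz(trace$time, trace$power)
}

#' Full width at half maximum of a pulse trace
#'
#' The half-max crossings on each side of the (first) maximum are found
#' by linear interpolation between the bracketing samples.
#'
#' @param trace A pulse trace.
#' @return FWHM in seconds.
#' @export
pulse_fwhm <- function(trace) {
  validate_pulse_trace(trace)
  fwhm_of_profile(trace$time, trace$power)
}

# shared FWHM engine for traces, ACFs, and image profiles
fwhm_of_profile <- function(x, y) {
  mx <- max(y)
  abort_if(mx <= 0, "Profile has no positive maximum; FWHM undefined.")
  half <- mx / 2
  above <- which(y >= half)
  abort_if(length(above) == 0L || above[1L] == 1L || above[length(above)] == length(y),
           "Profile does not cross half-maximum inside the sampled range.")
  i <- above[1L] # first sample at/above half
  j <- above[length(above)] # last sample at/above half
  left <- x[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
  right <- x[j] + (half - y[j]) / (y[j + 1L] - y[j]) * (x[j + 1L] - x[j])
  right - left
}

#' Average power of a pulse train
#'
#' For a train of identical pulses, average power is pulse energy times
#' repetition rate.
#'
#' @param trace A single-pulse trace.
#' @param rep_rate Repetition rate in Hz.
#' @return Average power in watts.
#' @examples
#' tr <- generate_pulse(pulse_spec("sech2", 125e-15, energy = 12.5e-9))
#' average_power(tr, 80e6) # 1 W
#' @export
average_power <- function(trace, rep_rate) {
  validate_pulse_trace(trace)
  abort_if(rep_rate <= 0, "`rep_rate` must be positive.")
  mx <- max(trace$power)
  if (mx > 0) {
    lit <- which(trace$power > DECAY_THRESHOLD * mx)
    span <- trace$time[lit[length(lit)]] - trace$time[lit[1L]]
    abort_if(span >= 1 / rep_rate,
             "Pulse is longer than the inter-pulse period at this repetition rate.")
  }
  pulse_energy(trace) * rep_rate
}

#' Closed-form sech-squared peak power
#'
#' For a sech-squared pulse, energy E, FWHM, and peak power are linked by
#' Ppk = E * 2*acosh(sqrt(2)) / (2 * FWHM). Exposed for cross-checks
#' against [generate_pulse()].
#'
#' @param energy Pulse energy, joules.
#' @param fwhm Pulse FWHM, seconds.
#' @return Peak power, watts.
#' @export
sech2_peak_power <- function(energy, fwhm) {
  energy * SECH2_FWHM_FACTOR / (2 * fwhm)
}

#' @export
print.pulse_trace <- function(x, ...) {
  lab <- attr(x, "label")
  e <- trapz(x$time, x$power)
  cat(sprintf("<pulse_trace%s: %d samples, span %.3g fs, energy %.4g nJ>\n",
              if (nzchar(lab %||% "")) paste0(" '", lab, "'") else "",
              nrow(x), diff(range(x$time)) * 1e15, e * 1e9))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
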