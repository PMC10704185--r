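# Shared fixtures, built in code.

# standard 12.5 nJ sech2 trace (the Fig.-style equal-energy pulse)
sech2_trace <- function(fwhm_fs, energy_nj = 12.5, n = 4096, span = 40) {
  generate_pulse(pulse_spec("sech2", fwhm_fs * 1e-15, energy = energy_nj * 1e-9),
                 grid_span = span, n_samples = n)
}

# small hand-built trace (any shape) as a plain tibble; bypasses the
# generator so oracle tests do not depend on it
tiny_sech2 <- function(fwhm = 100e-15, n = 256, span = 12) {
  t0 <- fwhm / (2 * acosh(sqrt(2)))
  half <- span * fwhm / 2
  time <- seq(-half, half, length.out = n)
  tibble::tibble(time = time, power = 1 / cosh(time / t0)^2)
}

# independent O(N^2) shift-multiply-trapezoid ACF oracle
acf_oracle <- function(trace) {
  p <- trace$power
  n <- length(p)
  dt <- (trace$time[n] - trace$time[1]) / (n - 1)
  vals <- vapply(seq.int(-(n - 1), n - 1), function(k) {
    if (k >= 0) {
      a <- p[seq_len(n - k)]
      b <- p[seq.int(1 + k, n)]
    } else {
      a <- p[seq.int(1 - k, n)]
      b <- p[seq_len(n + k)]
    }
    prod <- a * b
    m <- length(prod)
    if (m < 2) return(0)
    (sum(prod) - (prod[1] + prod[m]) / 2) * dt
  }, numeric(1))
  vals / max(vals)
}

# deterministic noiseless scene for image tests
quiet_scene <- function(shape = c(129L, 129L), amplitude = 20,
                        background = 96, read_noise_sd = 0, ...) {
  scene_spec(image_shape = shape, spot_amplitude = amplitude,
             background_level = background, read_noise_sd = read_noise_sd, ...)
}

# reference trapezoid used only inside tests
trapz_ref <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
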