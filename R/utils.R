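# internal numeric helpers

# trapezoidal integral; the package's only quadrature rule
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
}

# relative spread of grid spacing, used to validate uniform grids
grid_jitter <- function(x) {
  dx <- diff(x)
  (max(dx) - min(dx)) / mean(dx)
}
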