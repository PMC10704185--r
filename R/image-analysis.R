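# Excitation-volume image analysis.
#
# Raw frames are 16-bit unsigned count matrices from a 12-bit sensor
# scaled to 16 bits: counts are multiples of 16 with ceiling 65520.
# Normalization subtracts the mean of a background region (the outer
# border frame of the image, which is spot-free in this side-view
# geometry) and divides by the exposure in milliseconds, making frames
# taken at different exposures directly comparable.

SATURATION_CEILING <- 65520L

#' Is any pixel saturated?
#'
#' Saturation is tested against the 12-bit-in-16-bit ceiling (65520),
#' not the full 16-bit ceiling.
#'
#' @param pixels Integer/numeric matrix of raw counts.
#' @return Logical.
#' @export
is_saturated <- function(pixels) {
  any(pixels >= SATURATION_CEILING)
}

#' Background-subtract and exposure-normalize a raw frame
#'
#' @param pixels Matrix of raw 16-bit counts (>= 64 x 64).
#' @param exposure_ms Exposure time in milliseconds (> 0).
#' @param border_frac Fraction of each dimension treated as background
#'   border on every side (default 0.1).
#' @return Numeric matrix in counts/ms with attributes `background`
#'   (mean background counts) and `saturated` (logical; saturated frames
#'   should be excluded from intensity quantification). Negative values
#'   are permitted (noise around zero).
#' @export
normalize_image <- function(pixels, exposure_ms, border_frac = 0.1) {
  abort_if(!is.matrix(pixels), "`pixels` must be a matrix.")
  abort_if(nrow(pixels) < 64L || ncol(pixels) < 64L,
           "Image must be at least 64 x 64 pixels.")
  abort_if(exposure_ms <= 0, "`exposure_ms` must be positive.")
  abort_if(border_frac <= 0 || border_frac > 0.25,
           "`border_frac` must lie in (0, 0.25].")
  br <- max(1L, floor(nrow(pixels) * border_frac))
  bc <- max(1L, floor(ncol(pixels) * border_frac))
  mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  mask[c(seq_len(br), nrow(pixels) - seq_len(br) + 1L), ] <- TRUE
  mask[, c(seq_len(bc), ncol(pixels) - seq_len(bc) + 1L)] <- TRUE
  bg <- mean(pixels[mask])
  out <- (pixels - bg) / exposure_ms
  attr(out, "background") <- bg
  attr(out, "saturated") <- is_saturated(pixels)
  out
}

#' Brightest pixel of a normalized frame
#'
#' Ties are broken by first occurrence in row-major order (smallest row,
#' then smallest column).
#'
#' @param norm_img Normalized image matrix.
#' @return List: `value` (counts/ms), `row`, `col`.
#' @export
peak_intensity <- function(norm_img) {
  mx <- max(norm_img)
  hits <- which(norm_img == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, "row"], hits[, "col"]), , drop = FALSE]
  list(value = mx, row = unname(hits[1L, "row"]), col = unname(hits[1L, "col"]))
}

#' Lateral and axial FWHM through the brightest pixel
#'
#' Profiles are the raw single-pixel row and column through the peak
#' (no smoothing or 2-D fitting); half-max crossings are linearly
#' interpolated and converted to meters via the pixel size. By the
#' side-view imaging geometry the image row is the lateral (x) profile
#' and the column is the axial (z) profile.
#'
#' @param norm_img Normalized image matrix.
#' @param peak `list(row=, col=)` as from [peak_intensity()]; found
#'   automatically if `NULL`.
#' @param pixel_size Sample-plane pixel size, meters per pixel.
#' @return List: `fwhm_lateral`, `fwhm_axial` (meters).
#' @export
profile_fwhm <- function(norm_img, peak = NULL, pixel_size) {
  if (is.null(peak)) peak <- peak_intensity(norm_img)
  abort_if(peak$row <= 5L || peak$row > nrow(norm_img) - 5L ||
             peak$col <= 5L || peak$col > ncol(norm_img) - 5L,
           "Peak too close to the image edge for profile measurement.")
  row_profile <- norm_img[peak$row, ]
  col_profile <- norm_img[, peak$col]
  list(
    fwhm_lateral = fwhm_of_profile(seq_along(row_profile), row_profile) * pixel_size,
    fwhm_axial = fwhm_of_profile(seq_along(col_profile), col_profile) * pixel_size
  )
}

#' Optional Gaussian-fit FWHM cross-check
#'
#' Fits a 1-D Gaussian with offset to the peak row/column profiles by
#' nonlinear least squares. Provided only as a cross-check of the
#' interpolated-profile estimator; not used by the pipeline.
#'
#' @inheritParams profile_fwhm
#' @return List: `fwhm_lateral`, `fwhm_axial` (meters).
#' @export
profile_fwhm_gaussfit <- function(norm_img, peak = NULL, pixel_size) {
  if (is.null(peak)) peak <- peak_intensity(norm_img)
  fit1d <- function(y) {
    x <- seq_along(y)
    st <- list(a = max(y), mu = which.max(y), sigma = max(2, sum(y > max(y) / 2) / 2.355),
               b = stats::median(y))
    fit <- stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)) + b,
                      start = st, control = stats::nls.control(warnOnly = TRUE))
    2 * sqrt(2 * log(2)) * abs(stats::coef(fit)[["sigma"]])
  }
  list(
    fwhm_lateral = fit1d(norm_img[peak$row, ]) * pixel_size,
    fwhm_axial = fit1d(norm_img[, peak$col]) * pixel_size
  )
}

#' Measure one spot frame
#'
#' Runs normalization, peak extraction, and FWHM profiling on a raw
#' frame and returns one tidy measurement row.
#'
#' @param pixels Raw 16-bit count matrix.
#' @param exposure_ms Exposure, ms.
#' @param incident_power Incident average power at the sample, watts.
#' @param pixel_size Meters per pixel.
#' @param laser_label,session_id Bookkeeping labels.
#' @param border_frac Background border fraction.
#' @return One-row tibble: labels, `power`, `peak_intensity` (counts/ms),
#'   `peak_row`, `peak_col`, `fwhm_lateral`, `fwhm_axial` (m),
#'   `saturated`.
#' @export
analyze_spot <- function(pixels, exposure_ms, incident_power, pixel_size,
                         laser_label = "", session_id = "", border_frac = 0.1) {
  norm <- normalize_image(pixels, exposure_ms, border_frac)
  pk <- peak_intensity(norm)
  fw <- profile_fwhm(norm, pk, pixel_size)
  tibble::tibble(
    laser_label = laser_label,
    session_id = session_id,
    power = incident_power,
    peak_intensity = pk$value,
    peak_row = pk$row,
    peak_col = pk$col,
    fwhm_lateral = fw$fwhm_lateral,
    fwhm_axial = fw$fwhm_axial,
    saturated = attr(norm, "saturated")
  )
}

#' Power-series analysis of spot measurements
#'
#' Averages peak intensity per power level and fits the log-log power
#' law; flags departures from the quadratic 2p dependence (saturation,
#' quenching, or single-photon contamination).
#'
#' @param measurements Data frame with `power` (watts) and
#'   `peak_intensity` columns (>= 3 distinct powers); saturated rows
#'   (logical `saturated` column) are dropped with a warning.
#' @param slope_tolerance Flag threshold on |slope - 2| (default 0.1).
#' @return List: `slope`, `flagged`, `per_power` (tibble of per-power
#'   mean intensities), and the `ref_powerlaw` `fit`.
#' @export
power_series_analysis <- function(measurements, slope_tolerance = 0.1) {
  if ("saturated" %in% names(measurements) && any(measurements$saturated)) {
    rlang::warn(sprintf("Dropping %d saturated frame(s).",
                        sum(measurements$saturated)))
    measurements <- dplyr::filter(measurements, !.data$saturated)
  }
  per_power <- measurements |>
    dplyr::group_by(.data$power) |>
    dplyr::summarise(mean_intensity = mean(.data$peak_intensity),
                     n = dplyr::n(), .groups = "drop")
  fit <- reference_regression(
    dplyr::transmute(per_power, power = .data$power,
                     fluorescence = .data$mean_intensity))
  list(slope = fit$slope,
       flagged = abs(fit$slope - 2) > slope_tolerance,
       per_power = per_power,
       fit = fit)
}
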