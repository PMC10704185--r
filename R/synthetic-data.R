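# Synthetic study generator.
#
# Every input the pipeline consumes can be generated with known ground
# truth: pulse traces (clean or with side lobes tuned to a target ACF
# width), camera frames of the excitation volume (anisotropic Gaussian
# spot, Poisson shot noise, Gaussian read noise, 12-bit-in-16-bit
# quantization), and multi-laser measurement tables obeying the
# quadratic power law with a per-laser efficiency factor.

#' Published characteristics of the benchmarked commercial lasers
#'
#' Repetition rates, sech-squared-deconvolved pulse durations, and
#' center wavelengths of a Ti:Sa reference laser (Spectra Physics Mai
#' Tai) and five other commercial lasers, as used in the worked examples.
#'
#' @return Tibble: `label`, `rep_rate` (Hz), `pulse_duration` (s),
#'   `wavelength` (m).
#' @export
example_lasers <- function() {
  tibble::tibble(
    label = c("Mai Tai", "Chameleon", "FF Ultra", "YLMO", "Axon", "Alcor"),
    rep_rate = c(80.78, 80.36, 80.51, 50.61, 80.13, 78.93) * 1e6,
    pulse_duration = c(82, 291, 94, 111, 158, 88) * 1e-15,
    wavelength = c(920, 920, 920, 930, 920, 920) * 1e-9
  )
}

#' Describe a synthetic laser
#'
#' @param label Laser label.
#' @param rep_rate Repetition rate, Hz.
#' @param pulse_fwhm Pulse FWHM, seconds.
#' @param true_eta Ground-truth 2p excitation efficiency (multiplicative
#'   factor on the quadratic signal; the reference laser has 1).
#' @param side_lobe_fraction Fraction of pulse energy in side lobes, in
#'   [0, 1); affects generated pulse traces only.
#' @param noise_cv Coefficient of variation of multiplicative
#'   measurement noise in generated fluorescence tables.
#' @return A `laser_spec` list.
#' @export
laser_spec <- function(label, rep_rate, pulse_fwhm, true_eta = 1,
                       side_lobe_fraction = 0, noise_cv = 0) {
  abort_if(rep_rate <= 0 || pulse_fwhm <= 0, "Rate and FWHM must be positive.")
  abort_if(true_eta <= 0, "`true_eta` must be positive.")
  abort_if(side_lobe_fraction < 0 || side_lobe_fraction >= 1,
           "`side_lobe_fraction` must lie in [0, 1).")
  abort_if(noise_cv < 0, "`noise_cv` must be non-negative.")
  structure(list(label = label, rep_rate = rep_rate, pulse_fwhm = pulse_fwhm,
                 true_eta = true_eta, side_lobe_fraction = side_lobe_fraction,
                 noise_cv = noise_cv),
            class = "laser_spec")
}

#' Describe a synthetic camera scene
#'
#' @param image_shape Integer c(rows, cols); default 256 x 256.
#' @param spot_amplitude Peak signal rate in counts/ms at `ref_power`.
#' @param fwhm_lateral,fwhm_axial Spot FWHMs in pixels (defaults 8 and
#'   24: an elongated side-view excitation volume, roughly 3:1).
#' @param background_level Constant background offset, counts.
#' @param read_noise_sd Gaussian read noise SD, counts (default 2).
#' @param pixel_size Sample-plane pixel size, meters per pixel.
#' @param ref_power Power (watts) at which `spot_amplitude` applies.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(256L, 256L), spot_amplitude = 20,
                       fwhm_lateral = 8, fwhm_axial = 24,
                       background_level = 100, read_noise_sd = 2,
                       pixel_size = 0.2e-6, ref_power = 10e-3) {
  abort_if(any(image_shape < 64L), "Scene images must be at least 64 x 64.")
  margin_r <- (image_shape[1L] - fwhm_axial) / 2
  margin_c <- (image_shape[2L] - fwhm_lateral) / 2
  abort_if(margin_r < 5 || margin_c < 5,
           "Spot must fit inside the image with a 5-pixel margin.")
  structure(list(image_shape = as.integer(image_shape),
                 spot_amplitude = spot_amplitude,
                 fwhm_lateral = fwhm_lateral, fwhm_axial = fwhm_axial,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 pixel_size = pixel_size, ref_power = ref_power),
            class = "scene_spec")
}

#' Build a pulse trace, optionally tuned to a target ACF width
#'
#' Without a target this is [generate_pulse()]. With `target_acf_width`
#' (composite shapes only) all lobe delays and widths are scaled by a
#' common multiplier, found by bisection, until the measured ACF
#' half-max width matches the target within 0.5%.
#'
#' @param shape_spec A [pulse_spec()].
#' @param target_acf_width Target ACF width in seconds, or `NULL`.
#' @param grid_span,n_samples Grid parameters for [generate_pulse()].
#' @param tol Relative tolerance on the achieved ACF width.
#' @return A `pulse_trace`.
#' @export
make_pulse_trace <- function(shape_spec, target_acf_width = NULL,
                             grid_span = 40, n_samples = 8192, tol = 0.005) {
  if (is.null(target_acf_width)) {
    return(generate_pulse(shape_spec, grid_span, n_samples))
  }
  abort_if(shape_spec$shape != "composite",
           "`target_acf_width` tuning is defined for composite shapes only.")
  width_at <- function(s) {
    sp <- shape_spec
    sp$fwhm <- shape_spec$fwhm * s
    sp$lobes <- dplyr::mutate(shape_spec$lobes,
                              delay = .data$delay * s, fwhm = .data$fwhm * s)
    tr <- generate_pulse(sp, grid_span, n_samples)
    list(width = acf_width(intensity_acf(tr)), trace = tr)
  }
  lo <- 0.05; hi <- 20
  w_lo <- width_at(lo)$width; w_hi <- width_at(hi)$width
  abort_if(w_lo > target_acf_width || w_hi < target_acf_width,
           "Bisection cannot bracket the target ACF width with scale in [0.05, 20].")
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    res <- width_at(mid)
    if (abs(res$width - target_acf_width) / target_acf_width < tol) {
      return(res$trace)
    }
    if (res$width < target_acf_width) lo <- mid else hi <- mid
  }
  rlang::abort("Bisection on the ACF width did not converge.")
}

#' Composite pulse description with a given side-lobe energy fraction
#'
#' A main sech-squared lobe flanked by two symmetric sech-squared side
#' lobes (same FWHM as the main lobe, at delays of +/- 2 FWHM) whose
#' relative heights are chosen so they carry the requested fraction of
#' the total pulse energy.
#'
#' @param fwhm Main-lobe FWHM, seconds.
#' @param energy Total pulse energy, joules.
#' @param side_lobe_fraction Side-lobe energy fraction in [0, 1).
#' @param lobe_delay Side-lobe delay as a multiple of `fwhm` (default 2).
#' @return A [pulse_spec()] (plain sech-squared when the fraction is 0).
#' @export
composite_spec <- function(fwhm, energy, side_lobe_fraction, lobe_delay = 2) {
  if (side_lobe_fraction == 0) {
    return(pulse_spec("sech2", fwhm, energy = energy))
  }
  # equal-FWHM lobes: energy ratio equals height ratio
  h <- side_lobe_fraction / (2 * (1 - side_lobe_fraction))
  pulse_spec("composite", fwhm, energy = energy,
             lobes = tibble::tibble(
               delay = c(0, -lobe_delay, lobe_delay) * fwhm,
               relative_height = c(1, h, h),
               fwhm = fwhm))
}

# anisotropic Gaussian spot, peak 1, centered in the frame;
# rows carry the axial (z) direction, columns the lateral (x) direction
spot_profile <- function(shape, fwhm_lateral, fwhm_axial) {
  r0 <- (shape[1L] + 1) / 2
  c0 <- (shape[2L] + 1) / 2
  rz <- exp(-4 * log(2) * ((seq_len(shape[1L]) - r0) / fwhm_axial)^2)
  cx <- exp(-4 * log(2) * ((seq_len(shape[2L]) - c0) / fwhm_lateral)^2)
  outer(rz, cx)
}

# quantize to the 12-bit-in-16-bit convention: multiples of 16, ceiling 65520
quantize_counts <- function(x) {
  pmin(pmax(round(x / 16) * 16, 0), 65520)
}

#' Generate a synthetic spot-image power series
#'
#' Each frame is `background + amplitude * true_eta * (P / ref_power)^2
#' * G(x, z) * exposure + noise`, with G an anisotropic Gaussian of the
#' scene's FWHMs, Poisson shot noise on the signal, additive Gaussian
#' read noise, and quantization to 12-bit-in-16-bit counts.
#'
#' @param laser A [laser_spec()].
#' @param scene A [scene_spec()].
#' @param powers Incident powers, watts.
#' @param exposures Exposure times, ms (same length as `powers`).
#' @param seed Integer seed for the single random stream of this call
#'   (`NULL` to leave the RNG state alone).
#' @param brightness Extra multiplicative factor on the signal (used by
#'   [make_study()] to encode inter-laser repetition-rate and
#'   pulse-duration differences).
#' @param shot_noise Apply Poisson noise to the signal?
#' @param session_id Session label for the output rows.
#' @param allow_saturation Permit frames that hit the 65520 ceiling.
#' @return Tibble with one row per frame: `laser_label`, `session_id`,
#'   `power`, `exposure_ms`, `pixel_size`, and a `pixels` list-column of
#'   count matrices.
#' @export
make_spot_series <- function(laser, scene, powers, exposures, seed = NULL,
                             brightness = 1, shot_noise = TRUE,
                             session_id = "s1", allow_saturation = FALSE) {
  abort_if(length(powers) != length(exposures),
           "`powers` and `exposures` must have the same length.")
  if (!is.null(seed)) set.seed(seed)
  g <- spot_profile(scene$image_shape, scene$fwhm_lateral, scene$fwhm_axial)
  frames <- purrr::map(seq_along(powers), function(i) {
    rate <- scene$spot_amplitude * brightness * laser$true_eta *
      (powers[i] / scene$ref_power)^2 # counts/ms at the peak
    signal <- rate * g * exposures[i]
    if (shot_noise) {
      signal <- matrix(stats::rpois(length(signal), lambda = signal),
                       nrow = nrow(signal))
    }
    img <- scene$background_level + signal
    if (scene$read_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = scene$read_noise_sd)
    }
    counts <- quantize_counts(img)
    abort_if(!allow_saturation && any(counts >= SATURATION_CEILING),
             sprintf("Frame at %.3g W saturates; lower the amplitude/exposure or set allow_saturation = TRUE.",
                     powers[i]))
    counts
  })
  tibble::tibble(
    laser_label = laser$label,
    session_id = session_id,
    power = powers,
    exposure_ms = exposures,
    pixel_size = scene$pixel_size,
    pixels = frames
  )
}

#' Generate a multi-laser fluorescence measurement table
#'
#' Direct (image-free) emulation of the measured per-point fluorescence:
#' `F = C * true_eta * (R_ref * tau_ref) / (R * tau) * P^2` with
#' multiplicative Gaussian noise of the given coefficient of variation,
#' and an optional saturation term `1 / (1 + P / saturation_power)` for
#' exercising the quadratic-slope guard.
#'
#' @param lasers Laser table (`label`, `rep_rate`, `pulse_duration`).
#' @param reference Reference laser label (its `true_eta` should be 1).
#' @param true_eta Ground-truth efficiency, one value per laser row.
#' @param powers Power grid, watts (default six levels, 4-10 mW).
#' @param n_sessions Sessions per laser (points = powers x sessions).
#' @param noise_cv Multiplicative noise CV (default 0.01).
#' @param saturation_power Saturation scale, watts (`Inf` = none).
#' @param scale Overall fluorescence scale constant.
#' @param seed Integer seed.
#' @return List: `measurements` (laser_label, session_id, power,
#'   fluorescence) and `lasers` (the input table), ready for
#'   [eta_study()].
#' @export
make_measurement_table <- function(lasers, reference, true_eta,
                                   powers = seq(4e-3, 10e-3, length.out = 6),
                                   n_sessions = 1, noise_cv = 0.01,
                                   saturation_power = Inf, scale = 1e6,
                                   seed = NULL) {
  abort_if(length(true_eta) != nrow(lasers),
           "`true_eta` needs one value per laser.")
  abort_if(!reference %in% lasers$label, "Reference label not in `lasers`.")
  if (!is.null(seed)) set.seed(seed)
  ref <- lasers[lasers$label == reference, ]
  meas <- purrr::map_dfr(seq_len(nrow(lasers)), function(i) {
    l <- lasers[i, ]
    ideal <- (ref$rep_rate * ref$pulse_duration) / (l$rep_rate * l$pulse_duration)
    purrr::map_dfr(seq_len(n_sessions), function(s) {
      f <- scale * true_eta[i] * ideal * powers^2 / (1 + powers / saturation_power)
      if (noise_cv > 0) f <- f * (1 + stats::rnorm(length(f), sd = noise_cv))
      tibble::tibble(laser_label = l$label,
                     session_id = sprintf("s%d", s),
                     power = powers,
                     fluorescence = f)
    })
  })
  list(measurements = meas, lasers = tibble::as_tibble(lasers))
}

#' Write a complete synthetic study to disk
#'
#' Renders a spot-image power series for every laser (brightness encodes
#' `true_eta` and the ideal repetition-rate/pulse-duration scaling
#' relative to the reference), writes the frames as 16-bit TIFFs, and
#' writes the manifest and laser-metadata CSVs in the layout the
#' readers and the command-line interface consume.
#'
#' @param lasers List of [laser_spec()]s.
#' @param reference_label Label of the reference laser (must be present).
#' @param scene A [scene_spec()].
#' @param powers,exposures Per-frame powers (W) and exposures (ms).
#' @param dir Output directory (created if needed).
#' @param n_sessions Sessions per laser.
#' @param seed Integer seed (one global stream for the whole study).
#' @param shot_noise Apply Poisson noise?
#' @return List of paths: `manifest`, `lasers`, `images` (directory).
#' @export
make_study <- function(lasers, reference_label, scene,
                       powers = seq(4e-3, 10e-3, length.out = 6),
                       exposures = NULL, dir, n_sessions = 1, seed = NULL,
                       shot_noise = TRUE) {
  labels <- purrr::map_chr(lasers, "label")
  abort_if(anyDuplicated(labels) > 0L, "Duplicate laser labels.")
  abort_if(!reference_label %in% labels, "Reference label missing from `lasers`.")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(exposures)) {
    # brighter frames get shorter exposures, emulating the fill-the-range
    # exposure choice; range 600 ms to 5 s
    exposures <- stats::approx(range(powers), c(5000, 600), xout = powers)$y
  }
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- lasers[[which(labels == reference_label)]]
  rows <- purrr::map_dfr(lasers, function(l) {
    ideal <- (ref$rep_rate * ref$pulse_fwhm) / (l$rep_rate * l$pulse_fwhm)
    purrr::map_dfr(seq_len(n_sessions), function(s) {
      series <- make_spot_series(l, scene, powers, exposures, seed = NULL,
                                 brightness = ideal, shot_noise = shot_noise,
                                 session_id = sprintf("s%d", s))
      series$path <- sprintf("images/%s_%s_p%02d.tif",
                             gsub("[^A-Za-z0-9]+", "-", l$label),
                             series$session_id, seq_along(powers))
      purrr::walk2(series$pixels, series$path,
                   ~ write_spot_image(.x, file.path(dir, .y)))
      series
    })
  })
  manifest <- rows |>
    dplyr::transmute(path = .data$path, laser_label = .data$laser_label,
                     session_id = .data$session_id,
                     power_mw = .data$power * 1e3,
                     exposure_ms = .data$exposure_ms,
                     pixel_size_um = .data$pixel_size * 1e6)
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  laser_tbl <- tibble::tibble(
    label = purrr::map_chr(lasers, "label"),
    rep_rate_mhz = purrr::map_dbl(lasers, "rep_rate") / 1e6,
    pulse_fs = purrr::map_dbl(lasers, "pulse_fwhm") * 1e15,
    wavelength_nm = 920
  )
  lasers_path <- file.path(dir, "lasers.csv")
  readr::write_csv(laser_tbl, lasers_path)
  list(manifest = manifest_path, lasers = lasers_path, images = img_dir)
}
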