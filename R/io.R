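# Readers and writers.
#
# Pulse traces travel as two-column delimited text with a unit-bearing
# header (e.g. "time_fs,power_au"); spot images as single-frame 16-bit
# grayscale TIFF plus a manifest CSV; study reports as JSON + CSV.

TIME_UNITS <- c(s = 1, ms = 1e-3, us = 1e-6, ns = 1e-9, ps = 1e-12, fs = 1e-15)
POWER_UNITS <- c(w = 1, mw = 1e-3, uw = 1e-6, kw = 1e3, au = 1)

parse_unit_header <- function(name, prefix, table) {
  m <- regmatches(name, regexec(paste0("^", prefix, "_([A-Za-z]+)$"), name))[[1L]]
  abort_if(length(m) < 2L || !tolower(m[2L]) %in% names(table),
           sprintf(paste0("Column '%s' must be named '%s_<unit>' with unit one of: %s ",
                          "(e.g. '%s_%s')."),
                   name, prefix, paste(names(table), collapse = ", "),
                   prefix, names(table)[length(table)]))
  table[[tolower(m[2L])]]
}

#' Read a pulse trace from delimited text
#'
#' Expects two numeric columns whose header names declare the units,
#' e.g. `time_fs,power_au`. Arbitrary-unit (`au`) powers are accepted;
#' downstream fluorescence prediction power-normalizes them anyway.
#' Non-uniform (but monotone) time grids are resampled onto a uniform
#' grid by linear interpolation with a warning.
#'
#' @param path File path (CSV or whitespace/tab-delimited).
#' @return A `pulse_trace` tibble in SI units (seconds, watts).
#' @export
read_pulse_trace <- function(path) {
  abort_if(!file.exists(path), sprintf("No such file: %s", path))
  df <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  abort_if(ncol(df) < 2L, "Expected two columns: time_<unit>, power_<unit>.")
  t_scale <- parse_unit_header(names(df)[1L], "time", TIME_UNITS)
  p_scale <- parse_unit_header(names(df)[2L], "power", POWER_UNITS)
  t <- df[[1L]] * t_scale
  p <- df[[2L]] * p_scale
  abort_if(any(!is.finite(t)) || any(!is.finite(p)), "Non-numeric values in trace.")
  abort_if(any(diff(t) <= 0), "Time column must be strictly increasing.")
  if (grid_jitter(t) > 1e-9) {
    rlang::warn("Non-uniform time grid; resampling by linear interpolation.")
    tu <- seq(t[1L], t[length(t)], length.out = length(t))
    p <- stats::approx(t, p, xout = tu)$y
    t <- tu
  }
  new_pulse_trace(t, pmax(p, 0), label = basename(path))
}

#' Write a pulse trace to CSV
#'
#' @param trace A `pulse_trace`.
#' @param path Output path.
#' @param time_unit,power_unit Output units (defaults fs, W).
#' @return `path`, invisibly.
#' @export
write_pulse_trace <- function(trace, path, time_unit = "fs", power_unit = "w") {
  validate_pulse_trace(trace)
  abort_if(!time_unit %in% names(TIME_UNITS), "Unknown time unit.")
  abort_if(!power_unit %in% names(POWER_UNITS), "Unknown power unit.")
  out <- tibble::tibble(trace$time / TIME_UNITS[[time_unit]],
                        trace$power / POWER_UNITS[[power_unit]])
  names(out) <- c(paste0("time_", time_unit), paste0("power_", power_unit))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a count matrix as 16-bit grayscale TIFF
#'
#' @param pixels Integer/numeric matrix of counts in [0, 65535].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_image <- function(pixels, path) {
  abort_if(any(pixels < 0) || any(pixels > 65535), "Counts outside [0, 65535].")
  tiff::writeTIFF(pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read one 16-bit grayscale spot image
#'
#' @param path TIFF (or PNG) path.
#' @return Integer count matrix.
#' @export
read_spot_image <- function(path) {
  abort_if(!file.exists(path), sprintf("No such file: %s", path))
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  abort_if(length(dim(img)) != 2L,
           sprintf("%s: expected single-channel grayscale, got %d channels.",
                   basename(path), if (length(dim(img)) == 3L) dim(img)[3L] else 1L))
  bits <- attr(img, "bits.per.sample")
  abort_if(!is.null(bits) && bits != 16L,
           sprintf("%s: expected 16-bit pixel depth, got %d-bit.", basename(path), bits))
  matrix(as.integer(round(img)), nrow(img), ncol(img))
}

#' Read a spot-image manifest and its images
#'
#' The manifest CSV must have columns `path`, `laser_label`,
#' `session_id`, `power_mw`, `exposure_ms`, `pixel_size_um`; image paths
#' are resolved relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Tibble with SI-unit columns (`power` W, `pixel_size` m),
#'   `exposure_ms`, labels, and a `pixels` list-column.
#' @export
read_spot_manifest <- function(path) {
  abort_if(!file.exists(path), sprintf("No such file: %s", path))
  man <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("path", "laser_label", "session_id", "power_mw", "exposure_ms",
            "pixel_size_um")
  missing_cols <- setdiff(need, names(man))
  abort_if(length(missing_cols) > 0L,
           paste0("Manifest is missing column(s): ", paste(missing_cols, collapse = ", ")))
  abort_if(any(man$exposure_ms <= 0), "All exposure_ms values must be positive.")
  base <- dirname(path)
  full <- file.path(base, man$path)
  gone <- which(!file.exists(full))
  abort_if(length(gone) > 0L,
           paste0("Missing image file(s) at manifest row(s): ",
                  paste(sprintf("%d (%s)", gone, man$path[gone]), collapse = ", ")))
  tibble::tibble(
    laser_label = man$laser_label,
    session_id = as.character(man$session_id),
    power = man$power_mw * 1e-3,
    exposure_ms = man$exposure_ms,
    pixel_size = man$pixel_size_um * 1e-6,
    pixels = purrr::map(full, read_spot_image)
  )
}

#' Analyze every frame of a loaded manifest
#'
#' Maps [analyze_spot()] over the rows of a [read_spot_manifest()] (or
#' [make_spot_series()]) table.
#'
#' @param frames Tibble with `pixels`, `exposure_ms`, `power`,
#'   `pixel_size`, `laser_label`, `session_id` columns.
#' @param border_frac Background border fraction.
#' @return Tibble of per-frame spot measurements.
#' @export
analyze_spot_frames <- function(frames, border_frac = 0.1) {
  purrr::map_dfr(seq_len(nrow(frames)), function(i) {
    analyze_spot(frames$pixels[[i]], frames$exposure_ms[i], frames$power[i],
                 frames$pixel_size[i], frames$laser_label[i],
                 frames$session_id[i], border_frac = border_frac)
  })
}

#' Read study configuration from YAML
#'
#' Unspecified fields take the defaults below.
#'
#' @param path YAML path, or `NULL` for all defaults.
#' @return List: `reference_label`, `power_range` (W), `slope_tolerance`,
#'   `background_frame_fraction`, `deconvolution_shape`, `output_dir`.
#' @export
read_study_config <- function(path = NULL) {
  defaults <- list(
    reference_label = "Mai Tai",
    power_range = c(4e-3, 10e-3),
    slope_tolerance = 0.1,
    background_frame_fraction = 0.1,
    deconvolution_shape = "sech2",
    output_dir = "."
  )
  if (!is.null(path)) {
    abort_if(!file.exists(path), sprintf("No such file: %s", path))
    user <- yaml::read_yaml(path)
    defaults[names(user)] <- user
  }
  abort_if(defaults$slope_tolerance <= 0, "slope_tolerance must be positive.")
  abort_if(defaults$background_frame_fraction <= 0 ||
             defaults$background_frame_fraction > 0.25,
           "background_frame_fraction must lie in (0, 0.25].")
  defaults
}

#' Write the study report
#'
#' Emits a JSON summary (per-laser results plus provenance: package
#' version, reference label, slope tolerance, and the multiple-comparison
#' method) and two CSVs: the per-laser table and the upper-triangular
#' pairwise p-value matrix.
#'
#' @param study An [eta_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_report <- function(study, dir) {
  abort_if(!inherits(study, "eta_study"), "`study` must be an eta_study.")
  abort_if(nrow(study$summary) == 0L, "Empty results; nothing to write.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(dir), sprintf("Cannot create output directory %s.", dir))
  report <- list(
    reference = study$reference,
    reference_slope = study$ref_fit$slope,
    slope_tolerance = study$slope_tolerance,
    comparison_method = "pairwise Welch t-tests, Holm-adjusted",
    package_version = as.character(utils::packageVersion("etalaser")),
    lasers = study$summary
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  per_laser_path <- file.path(dir, "per_laser.csv")
  readr::write_csv(study$summary, per_laser_path)
  paths <- list(json = json_path, per_laser = per_laser_path)
  if (!is.null(study$pairwise)) {
    pw <- as.data.frame(study$pairwise$matrix)
    pw <- cbind(laser = rownames(study$pairwise$matrix), pw)
    pairwise_path <- file.path(dir, "pairwise.csv")
    readr::write_csv(pw, pairwise_path)
    paths$pairwise <- pairwise_path
  }
  invisible(paths)
}
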