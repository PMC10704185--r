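# Two-photon excitation efficiency (eta) against a reference laser.
#
# Measured fluorescence is normalized per point against the reference
# laser's log-log power regression (bringing the reference's own mean to
# 1), then scaled by (R_test * tau_test) / (R_ref * tau_ref) to give
# eta = F_test / F_ideal: the fraction of the ideal square-pulse-law
# fluorescence the laser actually delivers, with the reference defined
# to have eta = 1.

#' Log-log power-law regression of a reference laser
#'
#' Ordinary least squares of log10(fluorescence) on log10(power). For 2p
#' excitation without saturation or quenching the slope is 2.
#'
#' @param data Data frame with numeric `power` (watts) and `fluorescence`
#'   (arbitrary normalized intensity) columns; >= 3 distinct powers.
#' @return A `ref_powerlaw` list: `slope`, `intercept` (log10 scale),
#'   `power_range` (observed, watts), and the underlying `lm` fit.
#' @examples
#' d <- tibble::tibble(power = c(4, 6, 8, 10) * 1e-3,
#'                     fluorescence = 3e4 * (c(4, 6, 8, 10) * 1e-3)^2)
#' reference_regression(d)$slope # 2
#' @export
reference_regression <- function(data) {
  abort_if(!all(c("power", "fluorescence") %in% names(data)),
           "`data` needs `power` and `fluorescence` columns.")
  abort_if(any(data$power <= 0) || any(data$fluorescence <= 0),
           "Powers and fluorescence values must be positive for a log-log fit.")
  abort_if(length(unique(data$power)) < 3L,
           "Need at least 3 distinct power levels.")
  fit <- stats::lm(log10(fluorescence) ~ log10(power), data = data)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         power_range = range(data$power),
         fit = fit),
    class = "ref_powerlaw"
  )
}

# fluorescence predicted by a ref_powerlaw at given powers (watts)
predict_reference <- function(ref_fit, power) {
  10^(ref_fit$intercept + ref_fit$slope * log10(power))
}

#' Normalize fluorescence against the reference power law
#'
#' Divides every measurement by the fluorescence the reference fit
#' predicts at the same power, adding an `f_ratio` column. The reference
#' laser's own points normalize to mean 1 by construction.
#'
#' @param data Data frame with `power` (watts) and `fluorescence`.
#' @param ref_fit A [reference_regression()] fit.
#' @return `data` with an added `f_ratio` column.
#' @export
normalize_fluorescence <- function(data, ref_fit) {
  abort_if(!inherits(ref_fit, "ref_powerlaw"),
           "`ref_fit` must come from reference_regression().")
  outside <- data$power < ref_fit$power_range[1L] |
    data$power > ref_fit$power_range[2L]
  if (any(outside)) {
    rlang::warn(sprintf(
      "%d measurement(s) outside the reference power range [%.3g, %.3g] W; extrapolating.",
      sum(outside), ref_fit$power_range[1L], ref_fit$power_range[2L]))
  }
  dplyr::mutate(data, f_ratio = .data$fluorescence / predict_reference(ref_fit, .data$power))
}

# (R_test * tau_test) / (R_ref * tau_ref)
eta_scale_factor <- function(test, ref) {
  abort_if(is.null(test$rep_rate) || is.null(test$pulse_duration) ||
             is.null(ref$rep_rate) || is.null(ref$pulse_duration),
           "Both lasers need `rep_rate` and `pulse_duration`.")
  (test$rep_rate * test$pulse_duration) / (ref$rep_rate * ref$pulse_duration)
}

#' Compute 2p excitation efficiency from normalized fluorescence ratios
#'
#' Each per-point F_test/F_ref ratio is multiplied by
#' (R_test * tau_test) / (R_ref * tau_ref); the mean and standard
#' deviation over points are reported.
#'
#' @param f_ratios Numeric vector of per-point normalized fluorescence.
#' @param test,ref Laser records: lists or one-row data frames with
#'   `rep_rate` (Hz) and `pulse_duration` (s), optionally `label`.
#' @return One-row tibble: `label`, `f_ratio_mean`, `f_ratio_sd`,
#'   `eta_mean`, `eta_sd`, `n_points`.
#' @examples
#' compute_eta(0.57, list(rep_rate = 80.13e6, pulse_duration = 158e-15),
#'             list(rep_rate = 80.78e6, pulse_duration = 82e-15))$eta_mean
#' @export
compute_eta <- function(f_ratios, test, ref) {
  abort_if(length(f_ratios) < 1L, "`f_ratios` must be nonempty.")
  scale <- eta_scale_factor(test, ref)
  etas <- f_ratios * scale
  tibble::tibble(
    label = as.character(test$label %||% ""),
    f_ratio_mean = mean(f_ratios),
    f_ratio_sd = if (length(f_ratios) > 1L) stats::sd(f_ratios) else 0,
    eta_mean = mean(etas),
    eta_sd = if (length(etas) > 1L) stats::sd(etas) else 0,
    n_points = length(etas)
  )
}

#' Pairwise comparisons of per-point efficiency between lasers
#'
#' Welch two-sample t statistics for every pair of lasers with Holm
#' step-down adjustment (via `stats::pairwise.t.test` with
#' `pool.sd = FALSE`), laid out as an upper-triangular matrix.
#'
#' @param data Data frame with a grouping column `laser` and a numeric
#'   column `eta` (one row per point).
#' @return List with `matrix` (upper-triangular adjusted p-values,
#'   lasers in first-appearance order) and `tidy` (tibble with columns
#'   `laser1`, `laser2`, `p_adj`).
#' @export
pairwise_compare <- function(data) {
  abort_if(!all(c("laser", "eta") %in% names(data)),
           "`data` needs `laser` and `eta` columns.")
  labs <- unique(data$laser)
  abort_if(length(labs) < 2L, "Need at least two lasers.")
  counts <- table(data$laser)
  abort_if(any(counts < 3L), "Each laser needs at least 3 points.")
  g <- factor(data$laser, levels = labs)
  pt <- stats::pairwise.t.test(data$eta, g, pool.sd = FALSE,
                               p.adjust.method = "holm")
  k <- length(labs)
  m <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  # pairwise.t.test returns the lower triangle over levels 2..k vs 1..k-1
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      m[i, j] <- pt$p.value[labs[j], labs[i]]
    }
  }
  tidy_tbl <- tibble::as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE)) |>
    stats::setNames(c("laser1", "laser2", "p_adj")) |>
    dplyr::filter(!is.na(.data$p_adj))
  list(matrix = m, tidy = tidy_tbl)
}

#' Correlation between spot size and excitation efficiency
#'
#' Pearson product-moment correlation, used to check that efficiency
#' differences between lasers are not explained by focus size.
#'
#' @param etas,widths Equal-length numeric vectors (n >= 3).
#' @return Pearson r.
#' @export
spotsize_efficiency_correlation <- function(etas, widths) {
  abort_if(length(etas) != length(widths) || length(etas) < 3L,
           "Need equal-length vectors with at least 3 pairs.")
  abort_if(stats::sd(etas) == 0 || stats::sd(widths) == 0,
           "Zero variance: correlation undefined.")
  stats::cor(etas, widths)
}

#' Full efficiency study from measurement and laser tables
#'
#' Fits the reference power law, checks the quadratic power dependence
#' of every laser (saturation/quenching guard), normalizes all points,
#' converts them to per-point eta values, and summarizes per laser with
#' pairwise Welch/Holm comparisons.
#'
#' @param measurements Data frame: `laser_label`, `session_id`, `power`
#'   (watts), `fluorescence` (positive, arbitrary units).
#' @param lasers Data frame: `label`, `rep_rate` (Hz), `pulse_duration`
#'   (s), optionally `wavelength` (m).
#' @param reference Label of the reference laser (must appear in both
#'   tables); defined to have eta = 1 on average.
#' @param slope_tolerance Reject any laser whose log-log slope deviates
#'   from 2 by more than this (default 0.1); set `check_slope = FALSE`
#'   to skip the guard.
#' @param check_slope Whether to apply the saturation guard.
#' @return An `eta_study` object; see [tidy.eta_study()],
#'   [glance.eta_study()], [autoplot.eta_study()].
#' @examples
#' study <- make_measurement_table(
#'   lasers = example_lasers()[c(1, 3), ], reference = "Mai Tai",
#'   true_eta = c(1, 0.86), noise_cv = 0, seed = 1)
#' fit <- eta_study(study$measurements, study$lasers, "Mai Tai")
#' tidy(fit)
#' @export
eta_study <- function(measurements, lasers, reference,
                      slope_tolerance = 0.1, check_slope = TRUE) {
  abort_if(!all(c("laser_label", "power", "fluorescence") %in% names(measurements)),
           "`measurements` needs laser_label, power, fluorescence columns.")
  abort_if(!all(c("label", "rep_rate", "pulse_duration") %in% names(lasers)),
           "`lasers` needs label, rep_rate, pulse_duration columns.")
  abort_if(!reference %in% measurements$laser_label,
           sprintf("Reference laser '%s' has no measurements.", reference))
  abort_if(!reference %in% lasers$label,
           sprintf("Reference laser '%s' is missing from the laser table.", reference))
  abort_if(anyDuplicated(lasers$label) > 0L, "Duplicate laser labels.")
  if (!"session_id" %in% names(measurements)) measurements$session_id <- "s1"

  slopes <- measurements |>
    dplyr::group_by(.data$laser_label) |>
    dplyr::group_modify(~ tibble::tibble(slope = reference_regression(.x)$slope)) |>
    dplyr::ungroup()
  if (check_slope) {
    bad <- dplyr::filter(slopes, abs(.data$slope - 2) > slope_tolerance)
    abort_if(nrow(bad) > 0L, paste0(
      "Power-law slope outside 2 ± ", slope_tolerance,
      " (possible saturation/quenching) for: ",
      paste(sprintf("%s (%.3f)", bad$laser_label, bad$slope), collapse = ", ")))
  }

  ref_fit <- reference_regression(
    dplyr::filter(measurements, .data$laser_label == reference))

  points <- measurements |>
    normalize_fluorescence(ref_fit) |>
    dplyr::left_join(
      dplyr::select(lasers, label, rep_rate, pulse_duration),
      by = c(laser_label = "label")) |>
    dplyr::mutate(eta = .data$f_ratio * (.data$rep_rate * .data$pulse_duration) /
                    (lasers$rep_rate[lasers$label == reference] *
                       lasers$pulse_duration[lasers$label == reference]))

  summary <- points |>
    dplyr::group_by(laser = .data$laser_label) |>
    dplyr::summarise(
      f_ratio_mean = mean(.data$f_ratio),
      f_ratio_sd = stats::sd(.data$f_ratio),
      eta_mean = mean(.data$eta),
      eta_sd = stats::sd(.data$eta),
      n_points = dplyr::n(),
      .groups = "drop") |>
    dplyr::left_join(slopes, by = c(laser = "laser_label"))

  # degenerate (e.g. noiseless, zero-variance) groups give NaN p-values;
  # keep the study result usable and leave pairwise empty instead
  pairwise <- if (length(unique(points$laser_label)) >= 2L &&
                  all(table(points$laser_label) >= 3L)) {
    tryCatch(
      suppressWarnings(pairwise_compare(
        dplyr::transmute(points, laser = .data$laser_label, eta = .data$eta))),
      error = function(e) NULL)
  } else NULL

  structure(
    list(points = tibble::as_tibble(points),
         summary = summary,
         reference = reference,
         ref_fit = ref_fit,
         pairwise = pairwise,
         slope_tolerance = slope_tolerance),
    class = "eta_study"
  )
}

#' @export
print.eta_study <- function(x, ...) {
  cat(sprintf("<eta_study: %d lasers, reference '%s', ref slope %.3f>\n",
              nrow(x$summary), x$reference, x$ref_fit$slope))
  print(x$summary)
  invisible(x)
}

#' Tidy per-laser efficiency summary
#'
#' @param x An `eta_study`.
#' @param ... Unused.
#' @return Tibble with one row per laser: normalized fluorescence and
#'   eta means/SDs, point counts, and power-law slopes.
#' @export
tidy.eta_study <- function(x, ...) x$summary

#' One-row study-level summary
#'
#' @param x An `eta_study`.
#' @param ... Unused.
#' @return Tibble: reference label, its log-log slope, laser and point
#'   counts.
#' @export
glance.eta_study <- function(x, ...) {
  tibble::tibble(
    reference = x$reference,
    ref_slope = x$ref_fit$slope,
    n_lasers = nrow(x$summary),
    n_points = nrow(x$points)
  )
}
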