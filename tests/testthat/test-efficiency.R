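ref_laser <- list(label = "ref", rep_rate = 80.78e6, pulse_duration = 82e-15)

test_that("log-log regression recovers the power-law exponent", {
  p <- seq(4e-3, 10e-3, length.out = 6)
  quad <- tibble::tibble(power = p, fluorescence = 3.1e4 * p^2)
  expect_equal(reference_regression(quad)$slope, 2, tolerance = 1e-10)
  lin <- tibble::tibble(power = p, fluorescence = 5 * p)
  expect_equal(reference_regression(lin)$slope, 1, tolerance = 1e-10)
  expect_error(reference_regression(tibble::tibble(power = p, fluorescence = -p)),
               "positive")
  expect_error(reference_regression(quad[1:2, ]), "3 distinct")
})

test_that("slope estimates stay near 2 under 1% multiplicative noise", {
  withr::with_seed(42, {
    slopes <- replicate(300, {
      p <- rep(seq(4e-3, 10e-3, length.out = 6), 3) # n = 18
      f <- 2e4 * p^2 * (1 + rnorm(length(p), sd = 0.01))
      reference_regression(tibble::tibble(power = p, fluorescence = f))$slope
    })
    expect_equal(mean(slopes), 2, tolerance = 0.02 / 2)
    expect_lt(stats::sd(slopes), 0.05)
  })
})

test_that("normalization brings the reference to mean 1 and preserves ratios", {
  p <- seq(4e-3, 10e-3, length.out = 6)
  ref_pts <- tibble::tibble(power = p, fluorescence = 7e3 * p^2)
  fit <- reference_regression(ref_pts)
  expect_equal(mean(normalize_fluorescence(ref_pts, fit)$f_ratio), 1,
               tolerance = 1e-10)
  half <- tibble::tibble(power = p, fluorescence = 3.5e3 * p^2)
  expect_equal(normalize_fluorescence(half, fit)$f_ratio, rep(0.5, 6),
               tolerance = 1e-10)
  out_of_range <- tibble::tibble(power = 20e-3, fluorescence = 7e3 * (20e-3)^2)
  expect_warning(normalize_fluorescence(out_of_range, fit), "extrapolat")
})

test_that("noisy parameter recovery: a 0.75 fluorescence ratio is recovered", {
  withr::with_seed(7, {
    p <- rep(seq(4e-3, 10e-3, length.out = 6), 3)
    ref_pts <- tibble::tibble(power = p, fluorescence = 1e4 * p^2 *
                                (1 + rnorm(length(p), sd = 0.01)))
    test_pts <- tibble::tibble(power = p, fluorescence = 0.75e4 * p^2 *
                                 (1 + rnorm(length(p), sd = 0.01)))
    fit <- reference_regression(ref_pts)
    m <- mean(normalize_fluorescence(test_pts, fit)$f_ratio)
    expect_equal(m, 0.75, tolerance = 0.01 / 0.75)
  })
})

test_that("eta worked examples round to the published two-decimal values", {
  axon <- compute_eta(0.57, list(label = "Axon", rep_rate = 80.13e6,
                                 pulse_duration = 158e-15), ref_laser)
  expect_equal(round(axon$eta_mean, 2), 1.09)
  toptica <- compute_eta(0.75, list(label = "FF Ultra", rep_rate = 80.51e6,
                                    pulse_duration = 94e-15), ref_laser)
  expect_equal(round(toptica$eta_mean, 2), 0.86)
  self <- compute_eta(1, ref_laser, ref_laser)
  expect_equal(self$eta_mean, 1)
})

test_that("eta is reciprocal when roles are swapped", {
  test <- list(label = "t", rep_rate = 50.61e6, pulse_duration = 111e-15)
  f <- 0.4
  forward <- compute_eta(f, test, ref_laser)$eta_mean
  backward <- compute_eta(1 / f, ref_laser, test)$eta_mean
  expect_equal(forward * backward, 1, tolerance = 1e-12)
})

test_that("pairwise Welch/Holm comparisons behave on known group structures", {
  withr::with_seed(3, {
    same <- tibble::tibble(laser = rep(c("a", "b"), each = 12),
                           eta = rep(rnorm(12, 1, 0.05), 2))
    expect_equal(pairwise_compare(same)$tidy$p_adj, 1)
    apart <- tibble::tibble(
      laser = rep(c("a", "b"), each = 12),
      eta = c(rnorm(12, 1, 0.02), rnorm(12, 1 + 5 * 0.02, 0.02)))
    expect_lt(pairwise_compare(apart)$tidy$p_adj, 1e-4)
    three <- tibble::tibble(
      laser = rep(c("a", "b", "c"), each = 12),
      eta = c(rnorm(12, 1, 0.02), rnorm(12, 1, 0.02), rnorm(12, 1.5, 0.02)))
    res <- pairwise_compare(three)$tidy
    sig <- res$p_adj < 0.05
    involves_c <- res$laser1 == "c" | res$laser2 == "c"
    expect_true(all(sig[involves_c]))
    expect_false(any(sig[!involves_c]))
  })
  expect_error(pairwise_compare(tibble::tibble(laser = "a", eta = 1)),
               "at least")
})

test_that("the pairwise matrix is upper triangular in first-appearance order", {
  withr::with_seed(5, {
    d <- tibble::tibble(laser = rep(c("x", "y", "z"), each = 5),
                        eta = rnorm(15, rep(c(1, 1.2, 1.4), each = 5), 0.05))
    m <- pairwise_compare(d)$matrix
    expect_identical(rownames(m), c("x", "y", "z"))
    expect_true(all(is.na(m[lower.tri(m, diag = TRUE)])))
    expect_true(all(!is.na(m[upper.tri(m)])))
  })
})

test_that("spot-size correlation handles exact and degenerate inputs", {
  expect_equal(spotsize_efficiency_correlation(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spotsize_efficiency_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(spotsize_efficiency_correlation(c(1, 1, 1), c(1, 2, 3)),
               "Zero variance")
  expect_error(spotsize_efficiency_correlation(1:3, 1:4), "equal-length")
})

test_that("a noiseless study self-normalizes: reference eta is exactly 1 at every power", {
  study <- make_measurement_table(example_lasers()[c(1, 5), ], "Mai Tai",
                                  true_eta = c(1, 1.09), noise_cv = 0)
  fit <- eta_study(study$measurements, study$lasers, "Mai Tai")
  ref_pts <- dplyr::filter(fit$points, laser_label == "Mai Tai")
  expect_equal(ref_pts$f_ratio, rep(1, 6), tolerance = 1e-9)
  expect_equal(ref_pts$eta, rep(1, 6), tolerance = 1e-9)
  # eta power-invariance: zero variance across power levels for exact P^2 data
  expect_lt(stats::sd(dplyr::filter(fit$points, laser_label == "Axon")$eta), 1e-9)
  expect_equal(dplyr::filter(tidy(fit), laser == "Axon")$eta_mean, 1.09,
               tolerance = 1e-9)
})

test_that("end-to-end eta recovery from noisy measurement tables", {
  for (eta0 in c(0.5, 0.86, 1.09)) {
    study <- make_measurement_table(example_lasers()[c(1, 3), ], "Mai Tai",
                                    true_eta = c(1, eta0), n_sessions = 3,
                                    noise_cv = 0.01, seed = round(1e3 * eta0))
    fit <- eta_study(study$measurements, study$lasers, "Mai Tai")
    row <- dplyr::filter(tidy(fit), laser == "FF Ultra")
    expect_lt(abs(row$eta_mean - eta0), 2 * row$eta_sd)
  }
})

test_that("the saturation guard rejects non-quadratic power series", {
  sat <- make_measurement_table(example_lasers()[c(1, 3), ], "Mai Tai",
                                true_eta = c(1, 0.86), noise_cv = 0,
                                saturation_power = 5e-3)
  expect_error(eta_study(sat$measurements, sat$lasers, "Mai Tai"),
               "saturation|slope")
  # and passes when disabled
  fit <- eta_study(sat$measurements, sat$lasers, "Mai Tai", check_slope = FALSE)
  expect_s3_class(fit, "eta_study")
})

test_that("glance summarizes the study fit", {
  study <- make_measurement_table(example_lasers()[c(1, 3), ], "Mai Tai",
                                  true_eta = c(1, 0.86), noise_cv = 0)
  g <- glance(eta_study(study$measurements, study$lasers, "Mai Tai"))
  expect_equal(g$reference, "Mai Tai")
  expect_equal(g$ref_slope, 2, tolerance = 1e-9)
  expect_equal(g$n_lasers, 2L)
})
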