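test_that("voigt_value reduces to its Gaussian and Lorentzian limits", {
  E <- seq(-3, 3, by = 0.1) + 6540
  g <- voigt_peak(6540, 0.4, 0, 2.0)
  expect_equal(voigt_value(E, g), 2 * stats::dnorm(E, 6540, 0.4))
  l <- voigt_peak(6540, 0, 0.3, 1.5)
  expect_equal(voigt_value(E, l), 1.5 * (0.3 / pi) / ((E - 6540)^2 + 0.3^2))
  # sigma -> 0 approaches the Lorentzian density
  near <- voigt_peak(6540, 1e-4, 0.3, 1.5)
  expect_equal(voigt_value(E, near), voigt_value(E, l), tolerance = 1e-5)
  expect_error(voigt_peak(6540, 0, 0, 1), "positive")
})

test_that("voigt_value matches a numerical convolution oracle", {
  pk <- voigt_peak(0, 0.4, 0.25, 1)
  x <- c(-2.7, -1.1, -0.3, 0, 0.45, 1.3, 2.9)
  expect_equal(voigt_value(x, pk), voigt_convolution_oracle(x, 0, 0.4, 0.25),
               tolerance = 1e-6)
  # a second, broader-Lorentzian case
  pk2 <- voigt_peak(5, 0.2, 0.6, 3)
  x2 <- 5 + c(-3, -0.8, 0, 0.5, 2.2)
  expect_equal(voigt_value(x2, pk2),
               3 * voigt_convolution_oracle(x2, 5, 0.2, 0.6), tolerance = 1e-6)
})

test_that("evaluate_peakset sums peaks (and optional baseline) on the grid", {
  grid <- seq(6538, 6545, by = 0.05)
  expect_equal(evaluate_peakset(voigt_peakset(list()), grid)$intensities,
               rep(0, length(grid)))
  p1 <- voigt_peak(6540, 0.3, 0.2, 4)
  expect_equal(evaluate_peakset(voigt_peakset(list(p1)), grid)$intensities,
               voigt_value(grid, p1))
  set.seed(31)
  peaks <- lapply(1:3, function(i)
    voigt_peak(stats::runif(1, 6539, 6544), stats::runif(1, 0.2, 0.5),
               stats::runif(1, 0.1, 0.4), stats::rexp(1) + 1))
  ps <- voigt_peakset(peaks)
  manual <- rep(0, length(grid))
  for (pk in peaks) manual <- manual + voigt_value(grid, pk)
  expect_equal(evaluate_peakset(ps, grid)$intensities, manual)
  psb <- voigt_peakset(peaks, baseline = c(0.7, 0.1), baseline_origin = 6541)
  expect_equal(evaluate_peakset(psb, grid)$intensities,
               manual + 0.7 + 0.1 * (grid - 6541))
  expect_equal(evaluate_peakset(psb, grid, include_baseline = FALSE)$intensities,
               manual)
})

test_that("noiseless Voigt fits recover planted parameters", {
  grid <- seq(6537, 6546, by = 0.05)
  truth <- voigt_peak(6541.2, 0.35, 0.22, 15)
  s <- evaluate_peakset(voigt_peakset(list(truth)), grid)
  fit <- fit_voigt_peaks(s, n_peaks = 1L, fit_region = c(6538, 6545))
  expect_true(fit$converged)
  got <- fit$peaks[[1L]]
  for (fld in c("center", "sigma", "gamma", "amplitude"))
    expect_equal(got[[fld]], truth[[fld]], tolerance = 1e-6)

  tp <- three_peak_spectrum(grid)  # centres separated by ~2 eV (>= 2 fwhm)
  fit3 <- fit_voigt_peaks(tp$spectrum, n_peaks = 3L, fit_region = c(6538, 6545))
  centers <- sort(vapply(fit3$peaks, `[[`, 0, "center"))
  expect_equal(centers, c(6539.5, 6541.3, 6543.2), tolerance = 0.01)
})

test_that("a fit started at the exact solution stays there", {
  grid <- seq(6537, 6546, by = 0.05)
  tp <- three_peak_spectrum(grid)
  fit <- fit_voigt_peaks(tp$spectrum, init = tp$peaks,
                         fit_region = c(6538, 6545))
  expect_lt(fit$residual_rms, 1e-8)
  centers <- vapply(fit$peaks, `[[`, 0, "center")
  expect_equal(centers, vapply(tp$peaks$peaks, `[[`, 0, "center"),
               tolerance = 1e-8)
})

test_that("peak centres stay accurate under noise at the measured SNR", {
  grid <- seq(6537, 6546, by = 0.1)
  tp <- three_peak_spectrum(grid)
  peak_height <- max(tp$spectrum$intensities)
  true_centers <- c(6539.5, 6541.3, 6543.2)
  errs <- unlist(lapply(1:10, function(k) {
    set.seed(500 + k)
    noisy <- xas_spectrum(grid, tp$spectrum$intensities +
                            stats::rnorm(length(grid), 0, peak_height / 20))
    fit <- suppressWarnings(
      fit_voigt_peaks(noisy, n_peaks = 3L, fit_region = c(6538, 6545)))
    abs(sort(vapply(fit$peaks, `[[`, 0, "center")) - true_centers)
  }))
  expect_lt(stats::median(errs), 0.02)
})

test_that("non-convergence is flagged, not silent", {
  set.seed(77)
  grid <- seq(6538, 6545, by = 0.1)
  jagged <- xas_spectrum(grid, abs(stats::rnorm(length(grid))))
  expect_warning(
    fit <- fit_voigt_peaks(jagged, n_peaks = 3L, max_iter = 1L),
    "did not converge")
  expect_false(fit$converged)
})
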