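test_that("xas_spectrum enforces its invariants", {
  expect_s3_class(xas_spectrum(1:3, c(0, -1, 2)), "xas_spectrum")
  expect_error(xas_spectrum(c(1, 2), 1:3), "equal length")
  expect_error(xas_spectrum(c(1, 1, 2), 1:3), "strictly increasing")
  expect_error(xas_spectrum(c(1, NA, 2), 1:3), "finite")
})

test_that("resample reproduces linear data exactly and matches a per-point oracle", {
  s <- xas_spectrum(seq(0, 10, by = 0.5), 2 * seq(0, 10, by = 0.5) + 1)
  expect_equal(resample(s, s$energies)$intensities, s$intensities)
  q <- c(0.3, 2.71, 7.77, 9.99)
  expect_equal(resample(s, q)$intensities, 2 * q + 1, tolerance = 1e-12)

  set.seed(101)
  r <- random_spectrum(20L)
  q <- sort(stats::runif(7, min(r$energies) + 0.01, max(r$energies) - 0.01))
  expect_equal(resample(r, q)$intensities,
               interp_oracle(r$energies, r$intensities, q), tolerance = 1e-12)
  expect_error(resample(r, max(r$energies) + 1), "extrapolation")
})

test_that("boxcar_bin averages with a truncated edge window", {
  s <- xas_spectrum(1:5, c(0, 1, 2, 3, 4))
  expect_equal(boxcar_bin(s, 3)$intensities, c(0.5, 1, 2, 3, 3.5))
  const <- xas_spectrum(1:20, rep(2.5, 20))
  expect_equal(boxcar_bin(const, 7)$intensities, rep(2.5, 20))
  expect_equal(boxcar_bin(s, 1), s)
  expect_error(boxcar_bin(s, 4), "odd")
  expect_error(boxcar_bin(s, 7), "larger")
})

test_that("5-point binning reduces white-noise variance about fivefold", {
  set.seed(7)
  n <- 2e4
  s <- xas_spectrum(seq_len(n), stats::rnorm(n))
  b <- boxcar_bin(s, 5)
  inner <- 3:(n - 2)
  ratio <- stats::var(s$intensities[inner]) / stats::var(b$intensities[inner])
  expect_gt(ratio, 5 * 0.7)
  expect_lt(ratio, 5 * 1.3)
})

test_that("spec_area integrates by trapezoid with interpolated endpoints", {
  flat <- xas_spectrum(seq(0, 1, by = 0.1), rep(1, 11))
  expect_equal(spec_area(flat, c(0, 1)), 1.0)
  tri <- xas_spectrum(c(0, 1), c(0, 1))
  expect_equal(spec_area(tri, c(0, 1)), 0.5)

  set.seed(11)
  r <- random_spectrum(40L, c(0, 10))
  reg <- c(1.234, 8.9)
  expect_equal(spec_area(r, reg), riemann_area_oracle(r, reg),
               tolerance = 1e-4)
  expect_error(spec_area(r, c(5, 2)), "lo < hi")
  expect_error(spec_area(r, c(-1, 5)), "outside")
})

test_that("area_normalize hits the target exactly and is idempotent", {
  s <- xas_spectrum(seq(0, 1, by = 0.05), rep(2, 21))  # area 2 over [0,1]
  n1 <- area_normalize(s, c(0, 1), 1)
  expect_equal(n1$intensities, s$intensities / 2)
  expect_equal(area_normalize(n1, c(0, 1), 1)$intensities, n1$intensities)

  set.seed(3)
  r <- random_spectrum(30L, c(0, 5))
  r$intensities <- abs(r$intensities) + 0.1
  n2 <- area_normalize(r, c(0.5, 4.5), 3.7)
  expect_equal(spec_area(n2, c(0.5, 4.5)), 3.7, tolerance = 1e-12)
  z <- xas_spectrum(0:5, rep(0, 6))
  expect_error(area_normalize(z, c(0, 5)), "non-positive")
})

test_that("subtract_spectra is an exact pointwise difference", {
  set.seed(5)
  e <- seq(0, 5, by = 0.25)
  a <- xas_spectrum(e, stats::rnorm(length(e)))
  b <- xas_spectrum(e, stats::rnorm(length(e)))
  expect_equal(subtract_spectra(a, a)$intensities, rep(0, length(e)))
  shifted <- xas_spectrum(e, b$intensities + 0.5)
  expect_equal(subtract_spectra(shifted, b)$intensities, rep(0.5, length(e)))
  d <- subtract_spectra(a, b)
  manual <- vapply(seq_along(e), function(i) a$intensities[i] - b$intensities[i], 0)
  expect_identical(d$intensities, manual)
  far <- xas_spectrum(e + 100, b$intensities)
  expect_error(subtract_spectra(a, far), "overlap")
})

test_that("sum_spectra adds sites elementwise", {
  set.seed(9)
  e <- seq(6538, 6544, by = 0.1)
  parts <- lapply(1:4, function(i) xas_spectrum(e, stats::rnorm(length(e))))
  expect_equal(sum_spectra(parts[1]), parts[[1]])
  neg <- xas_spectrum(e, -parts[[1]]$intensities)
  expect_equal(sum_spectra(list(parts[[1]], neg))$intensities, rep(0, length(e)))
  total <- rep(0, length(e))
  for (p in parts) total <- total + p$intensities
  expect_equal(sum_spectra(parts)$intensities, total)
  expect_error(sum_spectra(list()), "non-empty")
})

test_that("broadening conserves intensity and has the right shape", {
  grid <- seq(6490, 6520, by = 0.05)
  st <- stick_spectrum("Mn1", 6505, 2.5)
  k <- broadening_kernel("gaussian", fwhm = 1.0)
  b <- broaden_sticks(st, k, grid)
  expect_equal(grid[which.max(b$intensities)], 6505, tolerance = 0.05)
  expect_equal(spec_area(b, c(6495, 6515)), 2.5, tolerance = 1e-6)
  # half maximum at half FWHM from the centre (Gaussian closed form)
  at <- function(E) stats::approx(b$energies, b$intensities, E)$y
  expect_equal(at(6505.5), at(6505) / 2, tolerance = 1e-9)
  # linearity: two sticks equal the sum of the single-stick curves
  st2 <- stick_spectrum("Mn1", c(6503, 6507), c(1, 3))
  b2 <- broaden_sticks(st2, k, grid)
  b2a <- broaden_sticks(stick_spectrum("Mn1", 6503, 1), k, grid)
  b2b <- broaden_sticks(stick_spectrum("Mn1", 6507, 3), k, grid)
  expect_equal(b2$intensities, b2a$intensities + b2b$intensities,
               tolerance = 1e-12)
  # empty stick list is a zero spectrum, not an error
  b0 <- broaden_sticks(stick_spectrum("Mn2", numeric(0), numeric(0)), k, grid)
  expect_equal(b0$intensities, rep(0, length(grid)))
  expect_error(broadening_kernel("gaussian", fwhm = 0), "positive")
})

test_that("broadening conserves total intensity for every kernel shape", {
  set.seed(21)
  e0 <- stats::runif(25, 6500, 6510)
  i0 <- stats::rexp(25)
  st <- stick_spectrum("Mn3", e0, i0)
  for (shape in c("gaussian", "lorentzian", "pseudo_voigt")) {
    k <- broadening_kernel(shape, fwhm = 0.8, mixing = 0.3)
    span <- if (shape == "gaussian") 10 else 4000  # Lorentzian tails are heavy
    grid <- seq(min(e0) - span, max(e0) + span,
                by = if (shape == "gaussian") 0.08 else 0.08)
    b <- broaden_sticks(st, k, grid)
    expect_equal(spec_area(b, range(grid)), sum(i0),
                 tolerance = if (shape == "gaussian") 1e-4 else 2e-3)
  }
})

test_that("broadening and summation commute", {
  set.seed(22)
  a <- stick_spectrum("Mn1", stats::runif(10, 6500, 6510), stats::rexp(10))
  b <- stick_spectrum("Mn1", stats::runif(10, 6500, 6510), stats::rexp(10))
  both <- stick_spectrum("Mn1", c(a$energies, b$energies),
                         c(a$intensities, b$intensities))
  k <- broadening_kernel("gaussian", fwhm = 1.0)
  grid <- seq(6495, 6515, by = 0.05)
  lhs <- broaden_sticks(both, k, grid)
  rhs <- sum_spectra(list(broaden_sticks(a, k, grid), broaden_sticks(b, k, grid)))
  expect_equal(lhs$intensities, rhs$intensities, tolerance = 1e-12)
})
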