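test_that("the common grid matches the published evaluation grid", {
  g <- build_common_grid()
  expect_length(g, 240L)
  expect_equal(g[1], 6538)
  expect_equal(g[240], 6544.5)
  expect_equal(diff(g), rep(6.5 / 239, 239), tolerance = 1e-9)
  expect_true(all(diff(g) > 0))
  expect_equal(build_common_grid(c(0, 1), 2), c(0, 1))
  expect_error(build_common_grid(c(2, 1)), "lo < hi")
})

test_that("rmsd_score matches an explicit loop oracle and is a metric", {
  g <- build_common_grid()
  set.seed(71)
  a <- xas_spectrum(g, stats::rnorm(240))
  b <- xas_spectrum(g, stats::rnorm(240))
  expect_identical(rmsd_score(a, a), 0)
  expect_equal(rmsd_score(xas_spectrum(g, a$intensities + 0.37), a), 0.37)
  acc <- 0
  for (i in 1:240) acc <- acc + (a$intensities[i] - b$intensities[i])^2
  expect_equal(rmsd_score(a, b), sqrt(acc / 240), tolerance = 1e-12)
  expect_equal(rmsd_score(a, b), rmsd_score(b, a))
  for (k in 1:25) {  # triangle inequality on random triples
    x <- xas_spectrum(g, stats::rnorm(240))
    y <- xas_spectrum(g, stats::rnorm(240))
    z <- xas_spectrum(g, stats::rnorm(240))
    expect_lte(rmsd_score(x, z), rmsd_score(x, y) + rmsd_score(y, z) + 1e-12)
  }
  expect_error(rmsd_score(a, xas_spectrum(g + 1, b$intensities)), "identical grid")
})

test_that("preedge_excess flags models with excess absorption", {
  e <- seq(6538, 6545, by = 0.05)
  base <- xas_spectrum(e, 5 + stats::dnorm(e, 6541.5, 0.8) * 10)
  same <- preedge_excess(base, base)
  expect_equal(same$excess, 0)
  expect_false(same$excluded)
  dbl <- xas_spectrum(e, 2 * base$intensities)
  ex <- preedge_excess(dbl, base)
  expect_equal(ex$excess, 1.0, tolerance = 1e-12)
  expect_true(ex$excluded)
  set.seed(73)
  m <- xas_spectrum(e, abs(stats::rnorm(length(e))) + 1)
  got <- preedge_excess(m, base, region = c(6540, 6543))
  oracle <- (spec_area(m, c(6540, 6543)) - spec_area(base, c(6540, 6543))) /
    spec_area(base, c(6540, 6543))
  expect_equal(got$excess, oracle, tolerance = 1e-12)
  zero <- xas_spectrum(e, rep(0, length(e)))
  expect_error(preedge_excess(m, zero), "non-positive")
})

test_that("a model whose own difference is the experiment ranks first with zero RMSD", {
  cfg <- synth_config(seed = 81)
  native <- generate_native_model(cfg)
  vars <- generate_binding_mode_variants(native, cfg)
  kernel <- cfg$kernel
  cal <- cfg$true_calibration
  grid <- build_common_grid()
  planted <- subtract_spectra(model_spectrum(vars$B2, kernel, cal, grid),
                              model_spectrum(native, kernel, cal, grid))
  rk <- rank_models(vars, native, planted, kernel, cal)
  expect_identical(rk$model_id[1L], "B2")
  expect_lt(rk$rmsd[1L], 1e-12)
  expect_identical(rk$rank[1L], 1L)
  # frozen calibration is carried identically by every row
  expect_true(all(rk$shift == cal$shift) && all(rk$scale == cal$scale))
})

test_that("identical models tie and are ordered deterministically by id", {
  cfg <- synth_config(seed = 82)
  native <- generate_native_model(cfg)
  twin1 <- model_entry("Z1", native$sites, "twin")
  twin2 <- model_entry("Z2", native$sites, "twin")
  grid <- build_common_grid()
  exp_diff <- xas_spectrum(grid, stats::rnorm(240, sd = 0.1))
  rk <- rank_models(list(twin2, twin1), native, exp_diff,
                    cfg$kernel, cfg$true_calibration)
  expect_equal(rk$rmsd[1L], rk$rmsd[2L])
  expect_identical(rk$model_id, c("Z1", "Z2"))
})

test_that("ranking order is invariant under a common positive rescaling", {
  cfg <- synth_config(seed = 83)
  native <- generate_native_model(cfg)
  vars <- generate_binding_mode_variants(native, cfg)
  grid <- build_common_grid()
  exp_diff <- subtract_spectra(
    model_spectrum(vars$C2, cfg$kernel, cfg$true_calibration, grid),
    model_spectrum(native, cfg$kernel, cfg$true_calibration, grid))
  exp_diff <- xas_spectrum(grid, exp_diff$intensities + stats::rnorm(240, sd = 0.05))
  rk1 <- rank_models(vars, native, exp_diff, cfg$kernel, cfg$true_calibration)
  c0 <- 3.7  # scale the experiment and the calculated side together
  scaled_exp <- xas_spectrum(grid, c0 * exp_diff$intensities)
  scaled_cal <- xas_calibration(cfg$true_calibration$shift,
                                cfg$true_calibration$scale * c0)
  rk2 <- rank_models(vars, native, scaled_exp, cfg$kernel, scaled_cal)
  expect_identical(rk1$model_id, rk2$model_id)
  expect_equal(rk2$rmsd, c0 * rk1$rmsd, tolerance = 1e-10)
})

test_that("a model that cannot be evaluated is reported, not fatal", {
  cfg <- synth_config(seed = 84)
  native <- generate_native_model(cfg)
  vars <- generate_binding_mode_variants(native, cfg)
  # a model with a missing site errors individually; the others still rank
  off <- vars$E3
  off$sites$Mn1 <- NULL
  grid <- build_common_grid()
  exp_diff <- xas_spectrum(grid, stats::rnorm(240, sd = 0.1))
  rk <- rank_models(list(vars$B1, off, vars$C2), native, exp_diff,
                    cfg$kernel, cfg$true_calibration)
  expect_equal(nrow(rk), 3L)
  bad <- rk[rk$model_id == "E3", ]
  expect_true(is.na(bad$rmsd) && bad$excluded)
  expect_match(bad$exclusion_reason, "failed")
  ok <- rk[rk$model_id != "E3", ]
  expect_true(all(is.finite(ok$rmsd)) && all(ok$rank %in% 1:2))
})
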