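test_that("the generator is deterministic given a seed", {
  cfg <- synth_config(seed = 91)
  m1 <- generate_native_model(cfg)
  m2 <- generate_native_model(cfg)
  expect_identical(m1, m2)
  m3 <- generate_native_model(synth_config(seed = 92))
  expect_false(identical(m1$sites$Mn1$energies, m3$sites$Mn1$energies))

  vars <- generate_binding_mode_variants(m1, cfg)
  sim1 <- simulate_experiment(vars$C2, m1, cfg)
  sim2 <- simulate_experiment(vars$C2, m1, cfg)
  expect_identical(sim1$native$one_flash$intensities,
                   sim2$native$one_flash$intensities)
  expect_identical(sim1$treated$zero_flash$intensities,
                   sim2$treated$zero_flash$intensities)
})

test_that("drawn intensities respect the configured bounds", {
  cfg <- synth_config(seed = 93, intensity_bounds = c(2, 50))
  m <- generate_native_model(cfg)
  for (st in m$sites) {
    expect_true(all(st$intensities >= 2))
    expect_true(all(st$intensities <= 50))
  }
})

test_that("binding-mode variants apply exactly the requested perturbation", {
  cfg <- synth_config(seed = 94)
  native <- generate_native_model(cfg)
  none <- generate_binding_mode_variants(native, cfg, magnitude = 0)
  for (v in none)
    for (site in names(v$sites))
      expect_equal(v$sites[[site]], native$sites[[site]])

  dbl <- list(list(model_id = "X", class = "test", sites = "Mn4",
                   denergy = 0, factor = 2))
  v <- generate_binding_mode_variants(native, cfg, modes = dbl)[[1L]]
  expect_equal(v$sites$Mn4$intensities, 2 * native$sites$Mn4$intensities)
  for (site in c("Mn1", "Mn2", "Mn3"))
    expect_equal(v$sites[[site]], native$sites[[site]])

  bad <- list(list(model_id = "Y", class = "test", sites = "Mn9",
                   denergy = 0.1, factor = 1))
  expect_error(generate_binding_mode_variants(native, cfg, modes = bad),
               "absent site|one of")

  # distinct specs give distinguishable broadened spectra
  vars <- generate_binding_mode_variants(native, cfg)
  grid <- build_common_grid()
  specs <- lapply(vars, model_spectrum, kernel = cfg$kernel,
                  calibration = cfg$true_calibration, grid = grid)
  for (i in 2:length(specs))
    expect_gt(rmsd_score(specs[[i - 1L]], specs[[i]]), 0)
})

test_that("the noiseless, background-free, uncontaminated limit is exact", {
  cfg <- synth_config(seed = 95, snr = Inf, edge_amplitude = 0,
                      f_contamination = 0)
  native <- generate_native_model(cfg)
  vars <- generate_binding_mode_variants(native, cfg)
  sim <- simulate_experiment(vars$B1, native, cfg)
  grid <- sim$treated$one_flash$energies
  clean <- model_spectrum(vars$B1, cfg$kernel, cfg$true_calibration, grid)
  expect_equal(sim$treated$one_flash$intensities, clean$intensities,
               tolerance = 1e-14)
})

test_that("the realised noise matches the configured signal-to-noise ratio", {
  cfg0 <- synth_config(seed = 96)
  native <- generate_native_model(cfg0)
  grid <- seq(cfg0$grid_range[1], cfg0$grid_range[2], by = cfg0$grid_step)
  sel <- grid >= 6538 & grid <= 6544.5
  clean_cfg <- synth_config(seed = 96, snr = Inf)
  clean <- simulate_experiment(native, native, clean_cfg)$native$one_flash
  peak <- max(clean$intensities -
                max(clean$intensities[grid < 6536]))  # rough background floor
  snrs <- vapply(1:20, function(k) {
    cfgk <- synth_config(seed = 9600 + k)
    simk <- simulate_experiment(native, native, cfgk)
    # same native model but fresh noise: measure residual against the clean curve
    resid <- simk$native$one_flash$intensities - clean$intensities
    sig <- max(clean$intensities[sel] - min(clean$intensities[sel]))
    sig / stats::sd(resid[sel])
  }, 0)
  expect_equal(mean(snrs), 20, tolerance = 0.15 * 20)
})

test_that("planted ground truth is recoverable in a small noiseless study", {
  # at effectively infinite SNR the full pipeline must rank the truth first
  cfg <- synth_config(seed = 97, snr = 1e6)
  native <- generate_native_model(cfg)
  vars <- generate_binding_mode_variants(native, cfg)
  sim <- simulate_experiment(vars$C2, native, cfg)
  region <- cfg$preedge_region
  pp_n <- suppressWarnings(preprocess_preedge(
    sim$native$one_flash, sim$native$zero_flash, preedge_region = region))
  pp_t <- suppressWarnings(preprocess_preedge(
    sim$treated$one_flash, sim$treated$zero_flash, preedge_region = region,
    init_peaks = pp_n$peaks))
  exp_diff <- subtract_spectra(pp_t$fitted, pp_n$fitted)
  raw_grid <- seq(region[1] - 43, region[2] - 27, by = cfg$grid_step)
  calc_raw <- boxcar_bin(model_spectrum(native, cfg$kernel, NULL, raw_grid), 5)
  calib <- fit_calibration(calc_raw, pp_n$fitted, region = region)
  rk <- rank_models(vars, native, exp_diff, cfg$kernel, calib, region = region,
                    broaden_grid = sim$native$one_flash$energies, bin_window = 5)
  best <- rk$model_id[order(rk$rmsd)][1L]
  expect_identical(best, "C2")
  expect_equal(calib$shift, 35.3, tolerance = 0.1)
})

test_that("with zero perturbation, recovery sits at chance", {
  cfg <- synth_config(seed = 98)
  res <- suppressWarnings(
    run_recovery_study(cfg, n_replicates = 12L, ratios = 0))
  # chance is 1/14; observing more than 5/12 successes is essentially impossible
  expect_lte(res$recovery, 5 / 12)
})
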