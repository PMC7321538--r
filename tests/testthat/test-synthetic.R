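test_that("light model evaluates the exponential response correctly", {
  # dark value A_max (1 - C0)
  expect_equal(light_response(0, 3.437, 1.151, 0.05), 3.437 * (1 - 1.151))
  # saturating light approaches A_max
  expect_equal(light_response(1e6, 3.437, 1.151, 0.05), 3.437, tolerance = 1e-9)
  # independent hand evaluation at PPFD = 200
  expect_equal(light_response(200, 3.437, 1.151, 0.05),
               3.437 - 3.437 * 1.151 * exp(-0.05 * 200 / 3.437))
})

test_that("noiseless light curves reproduce the model and are seed-stable", {
  p <- mn_profile()
  lv <- c(800, 400, 200, 100, 50, 0)
  c1 <- generate_light_curve(p, lv, seed = 11)
  expect_equal(c1$Anet, light_response(lv, p$A_max, p$C0, p$alpha))
  c2 <- generate_light_curve(p, lv, seed = 11)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  # noise is applied when requested, and differs across seeds
  pn <- mn_profile(anet_sd = 0.2)
  n1 <- generate_light_curve(pn, lv, seed = 11)
  n2 <- generate_light_curve(pn, lv, seed = 12)
  expect_false(identical(n1$Anet, n2$Anet))
  expect_error(generate_light_curve(p, numeric(0)), "non-empty")
  expect_error(generate_light_curve(p, c(100, -5)), "non-negative")
})

test_that("invalid profiles are rejected at construction", {
  expect_error(mn_profile_bad <- leaf_profile(
    treatment = "X", A_max = -1, alpha = 0.05, C0 = 1.1, Vcmax = 20,
    Jmax = 70, gm_true = 0.2, Gamma_star = 100, SLN = 1, chl = 30,
    Sc = 10, Clip = 0.3, rubisco_content = 10, rubisco_activity = 10),
    "A_max")
  expect_error(leaf_profile(
    treatment = "X", A_max = 3, alpha = -0.05, C0 = 1.1, Vcmax = 20,
    Jmax = 70, gm_true = 0.2, Gamma_star = 100, SLN = 1, chl = 30,
    Sc = 10, Clip = 0.3, rubisco_content = 10, rubisco_activity = 10),
    "alpha")
})

test_that("A-Ci generator honours the compensation point and limiting rates", {
  p <- mn_profile()
  p$Rd <- 0  # compensation-point check needs a non-respiring leaf
  curve <- generate_aci_curve(p, co2_levels = c(p$Gamma_star, 300, 600, 900),
                              seed = 1, ci_ratio = 1)
  expect_equal(curve$Anet[1], 0, tolerance = 1e-10)

  # in the carboxylation-limited region (A_net + Rd) scales with Vcmax
  p1 <- mn_profile()
  p2 <- mn_profile(); p2$Vcmax <- 2 * p1$Vcmax
  ci_low <- 130
  a1 <- farquhar_anet(ci_low, p1$Vcmax, p1$Jmax, p1$Rd, p1$Gamma_star)
  a2 <- farquhar_anet(ci_low, p2$Vcmax, p2$Jmax, p2$Rd, p2$Gamma_star)
  expect_equal(a2 + p2$Rd, 2 * (a1 + p1$Rd), tolerance = 1e-12)

  # determinism and monotonicity of the noiseless curve
  c1 <- generate_aci_curve(p, seed = 5)
  c2 <- generate_aci_curve(p, seed = 5)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  d <- c1[order(c1$Ci), ]
  expect_true(all(diff(d$Anet) >= -1e-9))

  expect_error(generate_aci_curve(p, co2_levels = c(10, 20, 30)),
               "degenerate")
})

test_that("fluorescence series keeps yield ordering and dark limits", {
  p <- mn_profile(fluor_sd = 0.05)
  for (seed in 1:20) {
    fl <- generate_fluorescence_series(p, seed = seed)
    expect_true(all(fl$Fo <= fl$Fop + 1e-9))
    expect_true(all(fl$Fop <= fl$Fs + 1e-9))
    expect_true(all(fl$Fs <= fl$Fmp + 1e-9))
    expect_true(all(fl$Fmp <= fl$Fm + 1e-9))
    dark <- fl[fl$PPFD == 0, ]
    expect_equal(dark$Fmp, dark$Fm)
    expect_equal(dark$Fop, dark$Fo)
  }
  # PhiPSII implied by the series declines with PPFD (noiseless)
  p0 <- mn_profile()
  fl <- generate_fluorescence_series(p0, seed = 1)
  phi <- (fl$Fmp - fl$Fs) / fl$Fmp
  o <- order(fl$PPFD)
  expect_true(all(diff(phi[o]) <= 1e-9))
  # adjacent seeds give different noisy series
  pn <- mn_profile(fluor_sd = 0.05)
  f1 <- generate_fluorescence_series(pn, seed = 7)
  f2 <- generate_fluorescence_series(pn, seed = 8)
  expect_false(identical(f1, f2))
})

test_that("treatment dataset has the right shape, provenance and noise structure", {
  profs <- default_profiles(anet_sd = 0.05, fluor_sd = 0.02)
  ds <- generate_treatment_dataset(profs, n_reps = 7, seed = 3)
  expect_s3_class(ds, "synthetic_leaf_dataset")
  expect_equal(nrow(ds$leaf_scalars), 21)         # 3 profiles x 7 reps
  expect_equal(length(ds$leaf_profiles), 21)
  expect_equal(ds$seed, 3)
  # byte-identical regeneration under the same seed
  ds2 <- generate_treatment_dataset(profs, n_reps = 7, seed = 3)
  expect_identical(ds$gas_exchange, ds2$gas_exchange)
  expect_identical(ds$fluorescence, ds2$fluorescence)
  expect_identical(ds$leaf_scalars, ds2$leaf_scalars)

  # zero noise everywhere -> identical replicates
  p0 <- mn_profile()
  d0 <- generate_treatment_dataset(list(p0), n_reps = 3, seed = 1)
  a <- split(d0$gas_exchange$Anet, d0$gas_exchange$leaf_id)
  expect_equal(a[[1]], a[[2]])
  expect_equal(a[[2]], a[[3]])

  expect_error(generate_treatment_dataset(list(), n_reps = 3), "non-empty")
  expect_error(generate_treatment_dataset(profs, n_reps = 1), "n_reps")
})

test_that("replicate draws reproduce the requested between-leaf SD", {
  p <- mn_profile(trait_sd = c(gm_true = 0.04))
  ds <- generate_treatment_dataset(list(p), n_reps = 200, seed = 9)
  s <- stats::sd(ds$leaf_scalars$gm_true)
  expect_lt(abs(s - 0.04) / 0.04, 0.2)
  expect_equal(mean(ds$leaf_scalars$gm_true), 0.26, tolerance = 0.05)
})

test_that("CSV round trip preserves the dataset", {
  profs <- default_profiles(anet_sd = 0.05)
  ds <- generate_treatment_dataset(profs, n_reps = 2, seed = 4)
  out <- withr::local_tempdir()
  write_dataset(ds, out)
  back <- read_dataset(out)
  expect_equal(back$gas_exchange$Anet, ds$gas_exchange$Anet, tolerance = 1e-12)
  expect_equal(back$fluorescence$Fs, ds$fluorescence$Fs, tolerance = 1e-12)
  expect_equal(back$leaf_scalars$SLN, ds$leaf_scalars$SLN, tolerance = 1e-12)
  expect_identical(back$gas_exchange$leaf_id, ds$gas_exchange$leaf_id)
})
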