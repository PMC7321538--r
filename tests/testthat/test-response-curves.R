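test_that("light-response fit recovers noiseless generating parameters", {
  p <- mn_profile()
  curve <- generate_light_curve(p, seed = 2)
  f <- fit_light_response(curve)
  expect_s3_class(f, "light_fit")
  expect_equal(f$A_max, p$A_max, tolerance = 1e-6)
  expect_equal(f$C0, p$C0, tolerance = 1e-6)
  expect_equal(f$alpha, p$alpha, tolerance = 1e-6)
  # Rd reported as the magnitude of the dark-model value
  expect_equal(f$Rd, abs(3.437 - 3.437 * 1.151), tolerance = 1e-6)
  expect_gt(f$r2, 0.999999)
})

test_that("light-response fit recovers random noiseless profiles", {
  set.seed(101)
  for (k in 1:10) {
    p <- random_profile()
    f <- fit_light_response(generate_light_curve(p, seed = k))
    expect_equal(f$A_max, p$A_max, tolerance = 1e-6)
    expect_equal(f$C0, p$C0, tolerance = 1e-6)
    expect_equal(f$alpha, p$alpha, tolerance = 1e-6)
  }
})

test_that("degenerate light curves are rejected with a fit error", {
  flat <- as_gas_exchange_curve(
    data.frame(PPFD = c(0, 50, 100, 300, 800), Anet = rep(2, 5)),
    series_type = "light")
  expect_error(fit_light_response(flat), "degenerate",
               class = "photraits_fit_error")
  short <- as_gas_exchange_curve(
    data.frame(PPFD = c(0, 100, 300), Anet = c(-0.5, 1, 2)),
    series_type = "light")
  expect_error(fit_light_response(short), "at least 5")
})

test_that("AQY is the OLS slope of the low-light region", {
  pts <- as_gas_exchange_curve(
    data.frame(PPFD = c(0, 20, 40, 300, 500, 800),
               Anet = c(-0.5, 0.5, 1.5, 3, 3.3, 3.4)),
    series_type = "light")
  expect_equal(estimate_aqy(pts, 100), 0.05)  # exactly collinear low points
  flat <- as_gas_exchange_curve(
    data.frame(PPFD = c(0, 20, 40, 800), Anet = c(1, 1, 1, 2)),
    series_type = "light")
  expect_equal(estimate_aqy(flat, 100), 0)
  expect_error(estimate_aqy(pts, 10), "at least 3")

  # shrinking the region, the slope approaches the analytic derivative at
  # the origin, alpha * C0
  p <- mn_profile()
  tiny <- generate_light_curve(p, ppfd_levels = c(0, 2, 4, 20, 50, 100,
                                                  200, 400, 800), seed = 1)
  expect_equal(estimate_aqy(tiny, 5), p$alpha * p$C0, tolerance = 0.05)
  # and the narrow-region slope is closer to it than the default region's
  expect_lt(abs(estimate_aqy(tiny, 5) - p$alpha * p$C0),
            abs(estimate_aqy(tiny, 100) - p$alpha * p$C0))
})

test_that("CE and the operational compensation point come from the initial slope", {
  d <- data.frame(Ci = c(50, 100, 150, 400, 700, 1000, 1300),
                  Anet = c(-1.3, -0.45, 0.4, 3.2, 4.8, 5.6, 5.9))
  curve <- as_gas_exchange_curve(d, series_type = "co2")
  f <- fit_co2_response(curve)
  # closed-form OLS on the three low-Ci points
  expect_equal(f$CE, 0.017, tolerance = 1e-12)
  expect_equal(f$Gamma_star, 2.15 / 0.017, tolerance = 1e-9)
  expect_false(f$diagnostics$gamma_extrapolated)
})

test_that("Farquhar segmented fit recovers Vcmax and Jmax from noiseless curves", {
  p <- mn_profile()
  curve <- generate_aci_curve(p, seed = 3)
  f <- fit_co2_response(curve)
  expect_equal(f$Vcmax, 20.771, tolerance = 0.01)
  expect_equal(f$Jmax, 74.518, tolerance = 0.01)
  expect_equal(f$Jmax_over_Vcmax, f$Jmax / f$Vcmax)
  expect_equal(f$Rd_fit, p$Rd, tolerance = 0.05)
  expect_equal(f$Gamma_star_photo, p$Gamma_star, tolerance = 0.01)
  # quotient of the tabulated pair
  expect_equal(74.518 / 20.771, 3.588, tolerance = 1e-3)
})

test_that("fits are invariant to step order and average duplicated steps", {
  p <- mn_profile()
  curve <- generate_aci_curve(p, seed = 6)
  shuffled <- curve[sample(nrow(curve)), ]
  shuffled <- as_gas_exchange_curve(shuffled, series_type = "co2")
  f1 <- fit_co2_response(curve)
  f2 <- fit_co2_response(shuffled)
  expect_equal(f1$CE, f2$CE)
  expect_equal(f1$Vcmax, f2$Vcmax, tolerance = 1e-8)

  lc <- generate_light_curve(p, seed = 6)
  sh <- as_gas_exchange_curve(lc[sample(nrow(lc)), ], series_type = "light")
  expect_equal(estimate_aqy(lc), estimate_aqy(sh))
})

test_that("noisy light curves still locate A_max within a few percent", {
  set.seed(55)
  errs <- replicate(40, {
    p <- mn_profile(anet_sd = 0.1)
    f <- fit_light_response(generate_light_curve(p, seed = sample.int(1e6, 1)))
    abs(f$A_max - p$A_max) / p$A_max
  })
  expect_lt(median(errs), 0.05)
})
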