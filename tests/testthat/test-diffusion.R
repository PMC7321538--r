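test_that("variable-J gm matches hand arithmetic and its identities", {
  v <- variable_j_gm(Anet = 2, Ci = 300, Gamma_star = 100, JT = 60, Rd = 0.5)
  expect_equal(v$Cc_variableJ, 100 * 80 / 50)
  expect_equal(v$gm, 2 / 140)
  # bracket collapses to Gamma* when Anet + Rd = 0
  v0 <- variable_j_gm(Anet = -0.5, Ci = 300, Gamma_star = 100, JT = 60,
                      Rd = 0.5)
  expect_equal(v0$Cc_variableJ, 100)
  expect_error(variable_j_gm(2, 300, 100, JT = 9, Rd = 0.5), "domain")
  expect_warning(variable_j_gm(2, 150, 100, JT = 60, Rd = 0.5), "negative gm")
})

test_that("variable-J round trip recovers gm_true to machine precision", {
  set.seed(3)
  for (k in 1:100) {
    gm <- stats::runif(1, 0.02, 0.5)
    ci <- stats::runif(1, 200, 400)
    gs <- stats::runif(1, 40, 130)
    jt <- stats::runif(1, 60, 250)
    rd <- stats::runif(1, 0, 1.5)
    a <- anet_from_gm(gm, ci, gs, jt, rd)
    if (jt <= 4 * (a + rd)) next
    v <- variable_j_gm(a, ci, gs, jt, rd)
    expect_equal(v$gm, gm, tolerance = 1e-12)
    # algebraic identity gm (Ci - Cc) = Anet
    expect_equal(v$gm * (ci - v$Cc_variableJ), a, tolerance = 1e-12)
  }
})

test_that("specificity S reproduces tabulated values and is decreasing in Gamma*", {
  expect_equal(specificity_S(124.399), 210000 / (2 * 124.399))
  expect_lt(abs(specificity_S(124.399) - 844.15) / 844.15, 0.002)
  expect_lt(abs(specificity_S(99.259) - 1057.25) / 1057.25, 0.002)
  expect_equal(specificity_S(210000 / 2), 1)
  g <- seq(40, 140, by = 5)
  expect_true(all(diff(specificity_S(g)) < 0))
  expect_error(specificity_S(0), "Gamma_star")
})

test_that("apparent specificity S* is the initial slope of Jc/Jo vs Ci/O", {
  x <- c(0.0005, 0.001, 0.002, 0.003)
  expect_equal(apparent_specificity_sstar(x, 739.39 * x), 739.39)
  expect_equal(apparent_specificity_sstar(x, rep(1.4, 4)), 0)
  expect_error(apparent_specificity_sstar(c(0.1, 0.2), c(1, 2)), "at least 3")
  # points on a quadratic: shrinking the region converges to the tangent at 0
  xx <- seq(0, 0.4, length.out = 200)
  yy <- 2 * xx + 5 * xx^2
  s_wide <- apparent_specificity_sstar(xx, yy, initial_region_max = 0.4)
  s_narrow <- apparent_specificity_sstar(xx, yy, initial_region_max = 0.02)
  expect_lt(abs(s_narrow - 2), abs(s_wide - 2))
  expect_equal(s_narrow, 2, tolerance = 0.05)
})

test_that("Cc from the specificity ratio is the tabulated quotient rule", {
  expect_equal(cc_from_specificity(250, 739.39, 844.15), 250 * 739.39 / 844.15)
  expect_equal(cc_from_specificity(300, 844.15, 844.15), 300)
  expect_equal(cc_from_specificity(250, 0, 844.15), 0)
  # linear in Ci
  expect_equal(cc_from_specificity(c(100, 200), 700, 900),
               c(1, 2) * cc_from_specificity(100, 700, 900))
  expect_error(cc_from_specificity(250, 700, 0), "S must be > 0")
})

test_that("liquid-phase conductance reproduces the tabulated products", {
  expect_equal(round(liquid_phase_conductance(0.31, 8.42), 2), 2.61)
  expect_equal(round(liquid_phase_conductance(0.46, 12.01), 2), 5.52)
  expect_equal(liquid_phase_conductance(0.3, 0), 0)
  expect_error(liquid_phase_conductance(-0.1, 5), ">= 0")
})

test_that("internal conductance and gm/Rubisco follow their formulas", {
  expect_equal(internal_conductance(3.437, 300, 265.45), 3.437 / 34.55)
  expect_equal(internal_conductance(3.437, 300, 0), 3.437 / 300)
  expect_error(internal_conductance(3.437, 250, 265.45), "domain")

  expect_equal(round(gm_per_rubisco(0.09, 6.931), 2), 12.99)
  expect_lt(abs(gm_per_rubisco(0.26, 10.057) - 25.81) / 25.81, 0.002)
  expect_equal(gm_per_rubisco(0, 5), 0)
  expect_error(gm_per_rubisco(0.1, 0), "rubisco_content")
})
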