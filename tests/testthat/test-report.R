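test_that("treatment summaries use sample SD and per-group n", {
  s <- summarize_treatments(c(2, 2, 2, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(s$mean, c(2, 2))
  expect_equal(s$sd, c(0, 1))
  expect_equal(s$n, c(3L, 3L), ignore_attr = TRUE)
  expect_error(summarize_treatments(1:3, rep("A", 3)), "at least 2")
  # means of a generated dataset recover the profile means within MC error
  p <- mn_profile(trait_sd = c(A_max = 0.241))
  ds <- generate_treatment_dataset(list(p), n_reps = 100, seed = 8)
  expect_equal(mean(ds$leaf_scalars$Amax_true), 3.437,
               tolerance = 3 * 0.241 / sqrt(100) / 3.437)
})

test_that("percent contrast against a reference treatment", {
  expect_lt(abs(percent_vs_reference(2.61, 5.52) - 52.7) / 52.7, 0.002)
  expect_lt(abs(percent_vs_reference(22.51, 40.51) - 44.4) / 44.4, 0.002)
  expect_equal(percent_vs_reference(5.52, 5.52), 0)
  # antisymmetry around the reference
  expect_equal(percent_vs_reference(4, 5), -percent_vs_reference(6, 5))
  expect_error(percent_vs_reference(1, 0), "division")
})

test_that("letter groups separate clearly distinct treatments", {
  vals <- c(0, 0.1, -0.1, 10, 10.1, 9.9, 20, 20.1, 19.9)
  grp <- rep(c("lo", "mid", "hi"), each = 3)
  l <- letter_groups(vals, grp)
  expect_equal(length(unique(l)), 3)
  expect_equal(unname(l["hi"]), "a")   # highest mean gets "a"
  # identical groups share one letter
  same <- letter_groups(rep(2, 9), grp)
  expect_true(all(same == "a"))
  expect_error(letter_groups(1:4, c("A", "A", "B", "C")), "n >= 2")
})

test_that("letter partition agrees with the multcomp oracle", {
  library(multcomp)
  set.seed(6)
  for (k in 1:5) {
    g <- factor(rep(c("A", "B", "C", "D"), each = 6))
    y <- stats::rnorm(24, mean = rep(c(0, 0.5, 2, 2.2), each = 6))
    ours <- letter_groups(y, as.character(g))
    fit <- stats::aov(y ~ g)
    oracle <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")))
    olet <- oracle$mcletters$Letters
    share <- function(l, a, b) {
      any(strsplit(l[[a]], "")[[1]] %in% strsplit(l[[b]], "")[[1]])
    }
    for (a in levels(g)) for (b in setdiff(levels(g), a)) {
      expect_equal(share(as.list(ours), a, b), share(as.list(olet), a, b),
                   info = paste("pair", a, b, "rep", k))
    }
  }
})

test_that("relative expression follows 2^-ddCt", {
  expect_equal(relative_expression_ddct(20, 18, 22, 20), 1)   # ddCt = 0
  expect_equal(relative_expression_ddct(21, 18, 22, 20), 0.5) # ddCt = 1
  expect_equal(relative_expression_ddct(18, 18, 22, 20), 4)   # ddCt = -2
  expect_error(relative_expression_ddct(NA, 18, 22, 20), "finite")
})
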