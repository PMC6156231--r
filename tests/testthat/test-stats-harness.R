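# Test-selection policy and comparison battery.

test_that("the normality gate routes to the documented test branches", {
  set.seed(51)
  g1 <- rnorm(30); g2 <- rnorm(30, 0.5)
  skew <- exp(rnorm(30, 0, 1.5))
  expect_equal(choose_test(list(g1, g2), paired = TRUE), "paired t-test")
  expect_equal(choose_test(list(g1, g2)), "t-test")
  expect_equal(choose_test(list(g1, skew), paired = TRUE),
               "Wilcoxon signed-rank")
  expect_equal(choose_test(list(g1, skew)), "Mann-Whitney U")
  expect_equal(choose_test(list(g1, g2, rnorm(30))), "one-way ANOVA")
  expect_equal(choose_test(list(skew, exp(rnorm(30)), exp(rnorm(30)))),
               "Kruskal-Wallis")
  # identical inputs always give the identical name
  expect_equal(choose_test(list(g1, skew)), choose_test(list(g1, skew)))
  expect_error(choose_test(list(g1, 1:2)), "n >= 3")
  expect_error(choose_test(list(g1, g2, g1), paired = TRUE),
               "exactly two")
  expect_error(choose_test(list(g1, rnorm(10)), paired = TRUE),
               "equal length")
})

test_that("run_comparison matches the underlying base tests", {
  set.seed(52)
  a <- rnorm(25, 1); b <- rnorm(25)
  res <- run_comparison(list(a, b), paired = TRUE, label = "demo")
  expect_equal(res$test, "paired t-test")
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$direction, 1)
  sk <- exp(rnorm(25, 0, 2))
  res2 <- run_comparison(list(sk, b))
  expect_equal(res2$test, "Mann-Whitney U")
  expect_equal(res2$p_value, suppressWarnings(wilcox.test(sk, b)$p.value))
  expect_output(print(res), "paired t-test")
})

test_that("interaction test finds a real interaction and handles degeneracy", {
  set.seed(53)
  d <- expand.grid(laser_on = c(FALSE, TRUE), size_deg = c(10, 40, 120),
                   rep = 1:40)
  d$evoked_hz <- 10 - 2 * d$laser_on * (d$size_deg == 10) + rnorm(nrow(d), 0, 1)
  expect_lt(interaction_test(d)$p_interaction, 0.01)
  # no interaction built in: p is not small, typically
  d$evoked_hz <- 10 + 2 * d$laser_on + rnorm(nrow(d), 0, 1)
  p0 <- interaction_test(d)$p_interaction
  expect_true(p0 > 0 && p0 <= 1)
  # zero-noise identical cells: p = 1 by convention
  d$evoked_hz <- 5
  expect_equal(interaction_test(d)$p_interaction, 1)
  # empty or thin cells refused
  expect_error(interaction_test(d[d$rep == 1 & !d$laser_on, ]),
               "2 levels")
  thin <- d[!(d$laser_on & d$size_deg == 10) | d$rep == 1, ]
  expect_error(interaction_test(thin), "2 observations")
})

test_that("bonferroni implements the alpha/m decision rule", {
  b <- bonferroni(c(0.02, 0.01), m = 3)
  expect_equal(b$reject, c(FALSE, TRUE))
  expect_equal(b$p_adjusted, c(0.06, 0.03))
  expect_equal(bonferroni(0.04, m = 1)$reject, TRUE)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m >= ")
})

test_that("a pure gain change leaves the shape-interaction null intact", {
  # dLGN-like cohorts: multiplicative laser effect, normalised curves
  # coincide, so rejections stay at the nominal rate (checked at
  # acceptance scale in the acceptance suite; a smoke run here)
  cfg <- sim_config(seed = 61, n_units = c(dLGN = 20))
  units <- make_units(cfg)
  tr <- simulate_trial_counts(cfg, units)
  cu <- unit_size_curves(tr)
  res <- shape_interaction_test(cu)
  expect_true(res$p_interaction >= 0 && res$p_interaction <= 1)
  expect_equal(res$n_units, 20)
})
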