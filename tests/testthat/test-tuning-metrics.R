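# Indices and derived summaries.

test_that("ssi arithmetic, flooring and domain errors", {
  expect_equal(ssi(10, 5), 0.5)
  expect_equal(ssi(7, 7), 0)
  expect_equal(round(ssi(30.5, 20.0), 4), 0.3443)
  expect_equal(ssi(10, -3), 1)       # negative large-size response floored
  expect_error(ssi(0, 1), "excluded")
  r <- ssi(c(10, 20), c(5, 5))
  expect_equal(r, c(0.5, 0.75))
})

test_that("osi and dsi reproduce the defining examples", {
  phi <- c(0, 90, 180, 270)
  expect_equal(osi(phi, c(5, 0, 0, 0)), 1)
  expect_equal(dsi(phi, c(5, 0, 0, 0)), 1)
  expect_equal(osi(seq(0, 330, 30), rep(2, 12)), 0, tolerance = 1e-12)
  expect_equal(dsi(seq(0, 330, 30), rep(2, 12)), 0, tolerance = 1e-12)
  expect_equal(osi(phi, c(1, 0, 1, 0)), 1)
  expect_equal(dsi(phi, c(2, 0, 1, 0)), 1 / 3)
  expect_error(osi(phi, c(0, 0, -1, 0)), "undefined")
})

test_that("indices are invariant under positive rescaling of responses", {
  set.seed(31)
  phi <- seq(0, 330, 30)
  for (i in 1:20) {
    r <- rgamma(12, 2, 1)
    k <- runif(1, 0.1, 50)
    expect_equal(osi(phi, k * r), osi(phi, r), tolerance = 1e-12)
    expect_equal(dsi(phi, k * r), dsi(phi, r), tolerance = 1e-12)
    expect_equal(ssi(k * r[1] + k * r[2], k * r[2]),
                 ssi(r[1] + r[2], r[2]), tolerance = 1e-12)
  }
})

test_that("osi agrees with an independent 1 - circular-variance oracle", {
  set.seed(101)
  phi <- seq(0, 330, 30)
  for (i in 1:200) {
    r <- runif(12, 0, 10)
    expect_equal(osi(phi, r), oracle_one_minus_cv(phi, r, 2),
                 tolerance = 1e-12)
    expect_equal(dsi(phi, r), oracle_one_minus_cv(phi, r, 1),
                 tolerance = 1e-12)
  }
})

test_that("percent reduction reproduces reported cohort percentages", {
  expect_equal(percent_reduction(17.4, 11.6), 33)
  expect_equal(percent_reduction(67.1, 55.1), 18)
  expect_equal(percent_reduction(18.0, 14.0), 22)
  expect_equal(percent_reduction(12.3, 12.3), 0)
  expect_equal(percent_reduction(20, 15, digits = NULL), 25)
  expect_error(percent_reduction(0, 1))
  expect_equal(fraction_to_percent(1, 28), 4)
  expect_equal(fraction_to_percent(0, 28), 0)
})

test_that("optimum alignment indexes sizes relative to the preferred size", {
  sizes <- c(10, 25, 40, 60, 90, 120)
  inc <- align_to_optimal(sizes, 1:6)
  expect_equal(max(inc$step), 0)  # monotone curve: optimum at largest size
  al <- align_to_optimal(sizes, c(1, 2, 9, 3, 2, 1))
  expect_equal(al$step, -2:3)
  expect_equal(preferred_size(sizes, c(5, 9, 9, 3, 2, 1)), 25)  # tie: smaller
  # population mean at step 0 equals the mean preferred response
  set.seed(8)
  curves <- lapply(1:30, function(i) {
    r <- rgamma(6, 3, 0.2)
    align_to_optimal(sizes, r)
  })
  pop <- population_align(curves)
  rp <- vapply(curves, function(a) a$R[a$step == 0], numeric(1))
  expect_equal(pop$mean_R[pop$step == 0], mean(rp))
})

test_that("gain estimation recovers a multiplicative factor", {
  set.seed(12)
  r_off <- rgamma(6, 5, 0.5)
  expect_equal(gain_estimate(r_off, 0.7 * r_off), 0.7, tolerance = 1e-12)
  expect_error(gain_estimate(rep(0, 3), rep(0, 3)), "undefined")
})

test_that("ssi change analysis pairs states, excludes unsuppressed units, and reports reductions", {
  sizes <- c(10, 25, 40, 60)
  cu <- rbind(
    data.frame(unit_id = "a", size_deg = sizes,
               R_off = c(2, 10, 6, 6), R_on = c(2, 8, 6, 5.6)),
    data.frame(unit_id = "b", size_deg = sizes,
               R_off = c(1, 2, 3, 4), R_on = c(1, 2, 3, 4)))  # SSI = 0
  res <- ssi_change_analysis(cu)
  expect_equal(res$unit_id, "a")
  expect_equal(res$ssi_off, 0.4)
  expect_equal(res$ssi_on, 0.3)
  expect_equal(res$delta_ssi, -0.1)
  expect_equal(res$pct_reduction, 25)
  res2 <- ssi_change_analysis(cu, exclude_zero = FALSE)
  expect_equal(nrow(res2), 2)
  all_flat <- ssi_change_analysis(cu[cu$unit_id == "b", ])
  expect_equal(nrow(all_flat), 0)
})

test_that("contrast matching finds representative high/low pairs on a 5%-step grid", {
  grid <- seq(5, 95, by = 5)
  r_off <- 10 + 0.2 * grid
  r_on <- 0.85 * r_off
  r_on[grid == 95] <- 0.75 * r_off[grid == 95]  # stronger effect at the top
  m <- contrast_match(grid, r_off, r_on)
  expect_equal(m$high_contrast_pct, 90)
  expect_equal(m$lower_contrast_pct, 70)
  # uniform 15% reduction on a saturating curve: highest contrast wins
  cc <- c(5, 20, 35, 50, 65, 80, 95)
  crf <- 30 * cc / (cc + 30)
  m2 <- contrast_match(cc, crf, 0.85 * crf)
  expect_equal(m2$high_contrast_pct, 95)
  expect_equal(m2$reduction_pct, 15, tolerance = 1e-9)
  # no laser effect: signalled, no pair
  expect_error(contrast_match(cc, crf, crf), class = "tg_no_contrast_match")
})

test_that("rf_map recovers the receptive field within one square width", {
  cfg <- sim_config(seed = 23, n_units = c(V1 = 1))
  units <- make_units(cfg)
  sn <- simulate_sparse_noise(cfg, units)
  est <- rf_map(sn$spikes$spike_time_s, sn$frames, latency_s = sn$latency_s,
                n_perm = 50)
  expect_lt(abs(est$center["az"] - units$rf_az_deg[1]), cfg$sn_square_deg)
  expect_lt(abs(est$center["el"] - units$rf_el_deg[1]), cfg$sn_square_deg)
  expect_gt(est$score, 5)
  # spikes unrelated to the frames: no significant peak
  set.seed(1)
  rnd <- sort(runif(500, 0, 300))
  est0 <- rf_map(rnd, sn$frames, n_perm = 50)
  expect_lt(est0$score, 3)
  expect_error(rf_map(numeric(0), sn$frames), "no spikes")
  # a single spike: the STA is that one lagged frame
  st1 <- sn$frames$onset_s[10] + sn$latency_s + 0.01
  est1 <- rf_map(st1, sn$frames, latency_s = sn$latency_s, n_perm = 10)
  lit10 <- sn$frames$lit[10, ]
  expect_equal(sort(which(est1$sta > 0)), sort(lit10))
})
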