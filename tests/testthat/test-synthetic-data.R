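# The generator: rate model, spike simulation, sparse noise, voltage.

test_that("rate model hits spont + peak at the optimum and rejects unknown areas", {
  u <- fixture_unit(area = "dLGN", peak = 20, spont = 4, gain = 1)
  ep <- data.frame(size_deg = u$pref_size_deg, direction_deg = u$pref_dir_deg,
                   contrast_pct = 95, laser_on = FALSE)
  expect_equal(rate_model(u, ep), u$spont_hz + u$peak_rate_hz,
               tolerance = 1e-6)
  bad <- u; bad$area <- "V2"
  expect_error(rate_model(bad, ep), "unknown area")
  expect_error(rate_model(u, ep[, 1:2]), "lack column")
})

test_that("laser scales the driven component of subcortical units by exactly laser_gain", {
  u <- fixture_unit(area = "dLGN", gain = 0.67)
  ep <- expand.grid(size_deg = c(10, 25, 40, 60, 90, 120),
                    direction_deg = c(0, 90), contrast_pct = c(35, 95),
                    laser_on = FALSE)
  off <- rate_model(u, ep) - u$spont_hz
  ep$laser_on <- TRUE
  on <- rate_model(u, ep) - u$spont_hz
  expect_equal(on, 0.67 * off, tolerance = 1e-12)
  # noiseless SSI is laser-invariant for a pure gain change
  r_off <- model_size_tuning(u, c(10, 25, 40, 60, 90, 120))
  r_on <- model_size_tuning(u, c(10, 25, 40, 60, 90, 120), laser_on = TRUE)
  expect_equal(ssi(max(r_on), r_on[6]), ssi(max(r_off), r_off[6]),
               tolerance = 1e-12)
})

test_that("V1 normalization turns a uniform gain drop into a size-dependent effect", {
  sizes <- c(10, 25, 40, 60, 90, 120)
  u <- fixture_unit(area = "V1", wc = 10, ws = 50, supp = 2.5, sigma = 1.2,
                    gain = 0.85)
  off <- model_size_tuning(u, sizes)
  on <- model_size_tuning(u, sizes, laser_on = TRUE)
  ip <- which.max(off)
  red <- 100 * (off - on) / off
  expect_gt(red[ip], red[length(sizes)])
  # SSI drops for every gain < 1
  for (g in c(0.5, 0.7, 0.85, 0.95)) {
    u$laser_gain <- g
    on_g <- model_size_tuning(u, sizes, laser_on = TRUE)
    expect_lt(ssi(on_g[ip], on_g[6]), ssi(off[ip], off[6]))
  }
})

test_that("a lower contrast reproduces the laser-on optimal response and its reduced suppression", {
  sizes <- c(10, 25, 40, 60, 90, 120)
  u <- fixture_unit(area = "V1", wc = 10, ws = 50, supp = 2.5, sigma = 1.2,
                    gain = 0.7)
  off <- model_size_tuning(u, sizes)
  on <- model_size_tuning(u, sizes, laser_on = TRUE)
  ip <- which.max(off)
  # continuous search for the contrast matching the laser-on optimum
  f <- function(cc) model_size_tuning(u, sizes[ip], contrast_pct = cc) - on[ip]
  c_low <- uniroot(f, c(1, 95), tol = 1e-6)$root
  matched <- model_size_tuning(u, sizes, contrast_pct = c_low)
  expect_lt(abs(matched[ip] - on[ip]) / on[ip], 0.02)
  expect_lt(ssi(matched[ip], matched[6]), ssi(off[ip], off[6]))
})

test_that("make_units is reproducible and respects declared invariants", {
  cfg <- sim_config(seed = 7, n_units = c(sSC = 5, V1 = 5))
  u1 <- make_units(cfg)
  u2 <- make_units(cfg)
  expect_identical(u1, u2)
  expect_true(all(u1$laser_gain > 0 & u1$laser_gain <= 1))
  expect_true(all(u1$peak_rate_hz >= 0))
  expect_true(all(u1$ssi_true >= 0 & u1$ssi_true < 1))
  expect_true(all(u1$osi_true >= 0 & u1$dsi_true >= 0))
})

test_that("epoch tables interleave the laser and preserve timing gaps", {
  cfg <- sim_config(seed = 3, n_units = c(dLGN = 1), n_trials = 2,
                    directions_deg = c(0, 180), contrasts_pct = 95)
  s <- simulate_session(cfg)
  ep <- s$epochs
  expect_true(all(diff(ep$onset_s) >= cfg$stimulus_duration_s + cfg$isi_s - 1e-9))
  # strict laser alternation
  expect_true(all(ep$laser_on == rep(c(FALSE, TRUE), nrow(ep) / 2)))
  expect_true(all(ep$duration_s > 0))
})

test_that("simulated spike counts match the analytic model mean", {
  cfg <- sim_config(seed = 11, n_units = c(dLGN = 1), n_trials = 1000,
                    sizes_deg = 40, directions_deg = 0, contrasts_pct = 95)
  units <- make_units(cfg)
  tr <- simulate_trial_counts(cfg, units)
  grid <- data.frame(size_deg = 40, direction_deg = 0, contrast_pct = 95,
                     laser_on = c(FALSE, TRUE))
  expected <- rate_model(units[1, ], grid) - units$spont_hz[1]
  for (k in 1:2) {
    x <- tr$evoked_hz[tr$laser_on == grid$laser_on[k]]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected[k]), 3 * se + 1e-9)
  }
})

test_that("the session simulator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, n_units = c(sSC = 2), n_trials = 1,
                    sizes_deg = c(10, 40), directions_deg = c(0, 180),
                    contrasts_pct = 95)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$epochs, s2$epochs)
  t1 <- simulate_trial_counts(cfg, s1$units)
  t2 <- simulate_trial_counts(cfg, s1$units)
  expect_identical(t1, t2)
})

test_that("sparse-noise movies have the stated frame count and geometry", {
  cfg <- sim_config(seed = 2, n_units = c(V1 = 2))
  units <- make_units(cfg)
  sn <- simulate_sparse_noise(cfg, units)
  expect_equal(nrow(sn$frames$lit), 300 * 5)  # 5 min at 5 fps
  n_cells <- length(sn$frames$cell_az)
  expect_equal(ncol(sn$frames$lit), max(1, round(n_cells / 31)))
  expect_true(all(sn$frames$lit >= 1 & sn$frames$lit <= n_cells))
})

test_that("voltage synthesis has the requested noise floor and flags collisions", {
  tr0 <- simulate_voltage(numeric(0), 1, noise_sd = 2, seed = 4)
  expect_equal(sd(tr0$samples), 2, tolerance = 0.05)
  expect_equal(tr0$n_collisions, 0)
  tr1 <- simulate_voltage(c(0.100, 0.1005), 1, seed = 4)
  expect_equal(tr1$n_collisions, 1)
  expect_error(simulate_voltage(0.1, 1, sampling_rate_hz = 10000),
               ">= 20000")
})
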