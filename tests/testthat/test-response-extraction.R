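# Evoked-response windows, tuning tables, inclusion.

test_that("evoked response is stimulus-window rate minus the 0.5 s pre-onset rate", {
  ep <- data.frame(onset_s = 1, duration_s = 1)
  spikes <- sort(c(runif(2, 0.5, 1), runif(10, 1, 2)))
  expect_equal(trial_response(spikes, ep)$evoked_hz, 10 - 4)
  expect_equal(trial_response(numeric(0), ep)$evoked_hz, 0)
  # epoch too early to measure a spontaneous window is dropped
  ep2 <- data.frame(onset_s = c(0.2, 1), duration_s = 1)
  expect_warning(r <- trial_response(spikes, ep2), "dropped")
  expect_equal(nrow(r), 1)
})

test_that("mean trial response converges to the driven model rate", {
  cfg <- sim_config(seed = 17, n_units = c(sSC = 1), n_trials = 500,
                    sizes_deg = 40, directions_deg = 0, contrasts_pct = 95)
  s <- simulate_session(cfg)
  tr <- trial_responses(s$spikes, s$epochs)
  grid <- data.frame(size_deg = 40, direction_deg = 0, contrast_pct = 95,
                     laser_on = FALSE)
  expected <- rate_model(s$units[1, ], grid) - s$units$spont_hz[1]
  x <- tr$evoked_hz[!tr$laser_on]
  expect_lt(abs(mean(x) - expected), 3 * sd(x) / sqrt(length(x)))
})

test_that("tuning tables aggregate trials correctly and ignore trial order", {
  tr <- rbind(fixture_trials(4, 25, direction = 0),
              fixture_trials(8, 25, direction = 90),
              fixture_trials(c(2, 4), 60, direction = 0))
  tab <- build_tuning_table(tr)
  expect_equal(tab$mean_hz[tab$size_deg == 60], 3)
  expect_equal(tab$n_trials[tab$size_deg == 60], 2)
  st <- size_tuning(tab, "u1")
  expect_equal(st$R_hz[st$size_deg == 25], 6)  # mean of 4 and 8
  shuf <- tr[sample(nrow(tr)), ]
  expect_equal(build_tuning_table(shuf), tab, ignore_attr = TRUE)
})

test_that("concatenating disjoint trial sets averages as a weighted mean", {
  a <- fixture_trials(c(1, 2, 3), 25)
  b <- fixture_trials(c(7, 9), 25)
  ta <- build_tuning_table(a); tb <- build_tuning_table(b)
  tboth <- build_tuning_table(rbind(a, b))
  expect_equal(tboth$mean_hz,
               (3 * ta$mean_hz + 2 * tb$mean_hz) / 5)
})

test_that("spikes outside the analysis windows do not affect responses", {
  ep <- data.frame(onset_s = c(2, 5), duration_s = 1,
                   size_deg = 40, direction_deg = 0, contrast_pct = 95,
                   laser_on = FALSE)
  base <- sort(runif(20, 2, 3))
  extra <- c(0.3, 1.1, 4.2, 6.5, 7.0)  # all in gaps, outside spont windows
  r1 <- trial_response(base, ep)
  r2 <- trial_response(sort(c(base, extra)), ep)
  expect_equal(r1$evoked_hz, r2$evoked_hz)
  expect_equal(r1$spont_hz, r2$spont_hz)
})

test_that("inclusion uses the laser-off peak with an inclusive 2 Hz threshold", {
  mk <- function(peak) build_tuning_table(rbind(
    fixture_trials(peak, 25, laser = FALSE),
    fixture_trials(1, 60, laser = FALSE),
    fixture_trials(50, 25, laser = TRUE)))  # laser-on must not rescue
  expect_true(include_unit(mk(2.0), "u1"))
  expect_false(include_unit(mk(1.9), "u1"))
  expect_false(include_unit(mk(-3), "u1"))
})
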