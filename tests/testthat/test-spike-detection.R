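# Threshold detection on synthetic traces.

test_that("degenerate traces yield no spikes", {
  expect_identical(detect_spikes(rep(0, 48000), 24000), numeric(0))
  expect_identical(detect_spikes(rep(3.3, 48000), 24000), numeric(0))
  expect_error(detect_spikes(numeric(0), 24000), "empty")
  expect_error(detect_spikes(c(rnorm(100), NA), 24000), "non-finite")
})

test_that("inserted 6-SD deflections are recovered at their insertion times", {
  true_t <- seq(0.005, by = 0.010, length.out = 20)
  tr <- simulate_voltage(true_t, 0.21, amplitude_sd = 6, seed = 42)
  det <- detect_spikes(tr)
  expect_length(det, 20)
  # each detection within 1 ms of an insertion (waveform trough lag)
  d <- vapply(det, function(t) min(abs(t - true_t)), numeric(1))
  expect_true(all(d < 1e-3))
})

test_that("crossings inside the refractory window collapse to one event", {
  true_t <- c(0.020, 0.0204)
  tr <- simulate_voltage(true_t, 0.05, amplitude_sd = 8, seed = 1)
  expect_length(detect_spikes(tr), 1)
})

test_that("detection is scale invariant and monotone in the threshold", {
  tr <- simulate_voltage(seq(0.05, 0.45, by = 0.02), 0.5,
                         amplitude_sd = 5, seed = 9)
  t1 <- detect_spikes(tr$samples, tr$sampling_rate_hz)
  t2 <- detect_spikes(tr$samples * 7.3, tr$sampling_rate_hz)
  expect_identical(t1, t2)
  counts <- vapply(c(2, 3, 4, 5, 6),
                   function(k) length(detect_spikes(tr, k_sd = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("closed loop with the voltage synthesiser: high-amplitude recall, low-amplitude failure", {
  set.seed(13)
  true_t <- sort(runif(50, 0.01, 9.97))
  true_t <- true_t[c(TRUE, diff(true_t) > 0.003)]
  hi <- simulate_voltage(true_t, 10, amplitude_sd = 6, seed = 21)
  det <- detect_spikes(hi)
  recall <- mean(vapply(hi$spike_times_s, function(t)
    any(abs(det - t) < 1e-3), logical(1)))
  expect_gte(recall, 0.95)
  lo <- simulate_voltage(true_t, 10, amplitude_sd = 1, seed = 21)
  det_lo <- detect_spikes(lo)
  recall_lo <- mean(vapply(lo$spike_times_s, function(t)
    any(abs(det_lo - t) < 1e-3), logical(1)))
  expect_lt(recall_lo, 0.5)
})

test_that("polarity and robust-scale options behave as documented", {
  tr <- simulate_voltage(seq(0.05, 0.25, by = 0.02), 0.3,
                         amplitude_sd = 6, seed = 2)
  neg <- detect_spikes(tr)
  ab <- detect_spikes(tr$samples, tr$sampling_rate_hz, polarity = "absolute")
  expect_true(all(neg %in% ab))
  pos <- detect_spikes(-tr$samples, tr$sampling_rate_hz,
                       polarity = "positive")
  expect_identical(neg, pos)
  # MAD is immune to the spike-inflated SD, so its threshold is lower and
  # it can only detect more
  rob <- detect_spikes(tr$samples, tr$sampling_rate_hz, robust = TRUE)
  expect_gte(length(rob), length(neg))
})
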