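# Repeated-simulation validation studies. These are the package's own
# closed-loop checks: each one generates data with the mechanistic
# generator, runs the analysis pipeline on it, and summarises how well the
# analysis recovers what the generator put in. They are used by the test
# suite and by scripts/acceptance.R.

#' Rejection rates of the laser x size interaction test across cohorts
#'
#' Repeatedly draws a fresh cohort for one area, simulates the interleaved
#' size-tuning protocol at the count level, and applies
#' [shape_interaction_test()]. For subcortical areas the laser effect is a
#' pure gain change, the interaction null holds, and the rejection rate
#' estimates the test's false-positive rate; for V1 the normalization
#' stage produces a real shape change and the rejection rate estimates
#' power.
#'
#' @param area Brain area to simulate.
#' @param n_units Cohort size per repetition.
#' @param n_reps Number of simulated cohorts.
#' @param seed Base seed (repetition r uses `seed + r`).
#' @return Numeric vector of interaction p-values, one per repetition.
#' @export
study_interaction <- function(area, n_units, n_reps, seed = 1L) {
  vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(seed = seed + r, n_units = setNames(n_units, area))
    units <- make_units(cfg)
    tr <- simulate_trial_counts(cfg, units)
    shape_interaction_test(unit_size_curves(tr))$p_interaction
  }, numeric(1))
}

#' Paired surround-suppression change in a simulated V1 cohort
#'
#' Simulates one V1 cohort under the interleaved protocol and runs the
#' paired SSI analysis (laser-off preferred size reused for the laser-on
#' index; units with zero baseline suppression excluded).
#'
#' @param n_units Cohort size.
#' @param seed Seed.
#' @param n_trials Trials per condition and laser state.
#' @return The [ssi_change_analysis()] table.
#' @export
study_ssi_change <- function(n_units = 150L, seed = 1L, n_trials = 10L) {
  cfg <- sim_config(seed = seed, n_units = c(V1 = n_units),
                    n_trials = n_trials)
  units <- make_units(cfg)
  tr <- simulate_trial_counts(cfg, units)
  ssi_change_analysis(unit_size_curves(tr))
}

#' Contrast-reduction versus gain-reduction equivalence study
#'
#' Simulates a V1 cohort with the full size x contrast crossing, builds
#' population size-tuning curves per contrast and laser state, applies
#' [contrast_match()] to the population contrast-response curves at the
#' population-optimal size, and compares per-unit surround suppression at
#' the chosen high contrast (laser off) with that at the matched lower
#' contrast (laser off).
#'
#' The recordings this procedure emulates were penetrations selected for a
#' roughly 15% laser-induced reduction at high contrast, so the study
#' cohort's mean laser gain defaults to 0.78, which places the
#' high-contrast population reduction in the middle of the matching band.
#'
#' @param n_units V1 cohort size.
#' @param seed Seed.
#' @param n_trials Trials per condition and laser state.
#' @param laser_gain_mean Mean geniculate gain of the study cohort.
#' @return List: `match` (the [contrast_match()] result),
#'   `ssi_high`, `ssi_lower` (per-unit SSI vectors at the two contrasts,
#'   laser off), `match_error_rel` (relative mismatch of the matched
#'   responses), and the population curves.
#' @export
study_contrast_equivalence <- function(n_units = 150L, seed = 1L,
                                       n_trials = 10L,
                                       laser_gain_mean = 0.78) {
  cfg <- sim_config(seed = seed, n_units = c(V1 = n_units),
                    n_trials = n_trials)
  units <- make_units(cfg)
  set.seed(cfg$seed + 1L)
  units$laser_gain <- pmin(1, pmax(0.05,
                                   rnorm(nrow(units), laser_gain_mean, 0.06)))
  # stream unit by unit to keep the size x contrast x direction crossing
  # manageable; collapse each unit to direction-averaged cell means
  cells <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    tr <- simulate_trial_counts(cfg, units[i, , drop = FALSE],
                                contrasts_pct = cfg$contrasts_pct,
                                n_trials = n_trials,
                                seed = cfg$seed + 1000L + i)
    dirm <- aggregate(tr["evoked_hz"],
                      tr[c("size_deg", "contrast_pct", "laser_on")], mean)
    dirm$unit_id <- units$unit_id[i]
    cells[[i]] <- dirm
  }
  cells <- do.call(rbind, cells)
  pop <- aggregate(cells["evoked_hz"],
                   cells[c("size_deg", "contrast_pct", "laser_on")], mean)
  cmax <- max(pop$contrast_pct)
  off_hi <- pop[!pop$laser_on & pop$contrast_pct == cmax, ]
  opt_size <- off_hi$size_deg[which.max(off_hi$evoked_hz)]
  crf <- function(laser) {
    sub <- pop[pop$laser_on == laser & pop$size_deg == opt_size, ]
    sub <- sub[order(sub$contrast_pct), ]
    sub$evoked_hz
  }
  ctr <- sort(unique(pop$contrast_pct))
  r_off <- crf(FALSE); r_on <- crf(TRUE)
  cm <- contrast_match(ctr, r_off, r_on)
  i_hi <- match(cm$high_contrast_pct, ctr)
  rel_err <- cm$match_error_hz / r_on[i_hi]
  unit_ssi_at <- function(cc) {
    sub <- cells[!cells$laser_on & cells$contrast_pct == cc, ]
    vapply(split(sub, sub$unit_id), function(cu) {
      cu <- cu[order(cu$size_deg), ]
      ip <- which.max(cu$evoked_hz)
      if (cu$evoked_hz[ip] <= 0) return(NA_real_)
      ssi(cu$evoked_hz[ip], cu$evoked_hz[nrow(cu)])
    }, numeric(1))
  }
  list(match = cm,
       ssi_high = unit_ssi_at(cm$high_contrast_pct),
       ssi_lower = unit_ssi_at(cm$lower_contrast_pct),
       match_error_rel = rel_err,
       optimal_size_deg = opt_size,
       contrasts_pct = ctr, crf_off = r_off, crf_on = r_on)
}

#' Ground-truth recovery study: SSI and laser gain
#'
#' High-trial-count simulation of a mixed cohort; compares the recovered
#' per-unit SSI with the generator's noiseless-model SSI and, for the
#' areas where the laser is a pure gain change, the fitted multiplicative
#' gain with the generator's `laser_gain`.
#'
#' @param n_units Named per-area cohort sizes.
#' @param n_trials Trials per condition (default 100).
#' @param seed Seed.
#' @return Data.frame per unit: `unit_id`, `area`, `ssi_true`, `ssi_hat`,
#'   `gain_true`, `gain_hat` (`NA` for V1, where the cortical effect is
#'   not a single gain).
#' @export
study_recovery <- function(n_units = c(sSC = 30, dLGN = 30, LP = 20,
                                       PBG = 20, V1 = 50),
                           n_trials = 100L, seed = 1L) {
  cfg <- sim_config(seed = seed, n_units = n_units, n_trials = n_trials)
  units <- make_units(cfg)
  rows <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    tr <- simulate_trial_counts(cfg, units[i, , drop = FALSE],
                                n_trials = n_trials,
                                seed = cfg$seed + 2000L + i)
    cu <- unit_size_curves(tr)
    ip <- which.max(cu$R_off)
    ssi_hat <- if (cu$R_off[ip] > 0)
      ssi(cu$R_off[ip], cu$R_off[nrow(cu)]) else NA_real_
    gain_hat <- if (units$area[i] == "V1") NA_real_
    else gain_estimate(cu$R_off, cu$R_on)
    rows[[i]] <- data.frame(unit_id = units$unit_id[i],
                            area = units$area[i],
                            ssi_true = units$ssi_true[i],
                            ssi_hat = ssi_hat,
                            gain_true = units$laser_gain[i],
                            gain_hat = gain_hat,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type-I error of the gated comparison under null simulations
#'
#' Repeatedly simulates small paired cohorts with the laser gain forced to
#' 1 (no effect anywhere), compares per-unit optimal-size responses
#' between the interleaved laser-off and laser-on trials with
#' [run_comparison()], and returns the p-values. The rejection rate at
#' 0.05 estimates the selection policy's realised type-I error.
#'
#' @param n_reps Number of null cohorts.
#' @param n_units Units per cohort.
#' @param seed Base seed.
#' @return Numeric vector of p-values.
#' @export
study_null_calibration <- function(n_reps = 500L, n_units = 12L,
                                   seed = 1L) {
  vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(seed = seed + r, n_units = c(dLGN = n_units),
                      sizes_deg = 40, directions_deg = c(0, 90, 180, 270))
    units <- make_units(cfg)
    units$laser_gain <- 1
    tr <- simulate_trial_counts(cfg, units)
    m <- aggregate(tr["evoked_hz"], tr[c("unit_id", "laser_on")], mean)
    off <- m$evoked_hz[!m$laser_on][order(m$unit_id[!m$laser_on])]
    on <- m$evoked_hz[m$laser_on][order(m$unit_id[m$laser_on])]
    run_comparison(list(off = off, on = on), paired = TRUE)$p_value
  }, numeric(1))
}

#' Spike-detection recall on synthetic high-amplitude spikes
#'
#' Generates a Poisson spike train at a realistic multi-unit rate, embeds
#' it in Gaussian noise at the requested amplitude, runs the 3 x SD
#' detector and reports recall (fraction of true spikes with a detection
#' within 1 ms).
#'
#' @param duration_s Trace length.
#' @param rate_hz True spike rate.
#' @param amplitude_sd Spike amplitude in noise SDs.
#' @param seed Seed.
#' @return List with `recall`, `n_true`, `n_detected`.
#' @export
study_detection_recall <- function(duration_s = 10, rate_hz = 5,
                                   amplitude_sd = 6, seed = 1L) {
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_s)
  st <- sort(runif(n, 0, duration_s))
  st <- st[c(TRUE, diff(st) > 0.0025)]  # enforce a refractory period
  tr <- simulate_voltage(st, duration_s, amplitude_sd = amplitude_sd,
                         seed = seed + 1L)
  det <- detect_spikes(tr)
  hits <- vapply(tr$spike_times_s, function(t)
    any(abs(det - t) < 1e-3), logical(1))
  list(recall = mean(hits), n_true = length(tr$spike_times_s),
       n_detected = length(det))
}
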