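# Session simulators. All randomness is seeded from the config seed with
# fixed offsets per generator so each product is independently reproducible.

# Build the interleaved grating epoch table: every stimulus condition is
# presented n_trials times with laser off and n_trials times with laser on,
# and laser-on epochs strictly alternate with laser-off epochs. Condition
# order is shuffled independently within each trial block.
tg_make_epochs <- function(config) {
  sizes <- config$sizes_deg
  dirs <- config$directions_deg
  cond <- rbind(
    expand.grid(size_deg = sizes, direction_deg = dirs,
                contrast_pct = config$grating_contrast_pct),
    expand.grid(size_deg = config$contrast_size_deg, direction_deg = dirs,
                contrast_pct = setdiff(config$contrasts_pct,
                                       config$grating_contrast_pct)))
  dur <- config$stimulus_duration_s
  isi <- config$isi_s
  blocks <- vector("list", config$n_trials)
  for (tr in seq_len(config$n_trials)) {
    ord <- sample.int(nrow(cond))
    b <- cond[rep(ord, each = 2L), , drop = FALSE]
    b$laser_on <- rep(c(FALSE, TRUE), times = nrow(cond))
    b$trial <- tr
    blocks[[tr]] <- b
  }
  ep <- do.call(rbind, blocks)
  ep$onset_s <- isi + (seq_len(nrow(ep)) - 1L) * (dur + isi)
  ep$duration_s <- dur
  ep$epoch_id <- seq_len(nrow(ep))
  rownames(ep) <- NULL
  ep[, c("epoch_id", "onset_s", "duration_s", "size_deg", "direction_deg",
         "contrast_pct", "laser_on", "trial")]
}

#' Simulate a full interleaved-laser recording session
#'
#' Generates the grating epoch table for a configuration and draws spike
#' trains for every ground-truth unit as an inhomogeneous Poisson process:
#' a homogeneous background at the unit's spontaneous rate over the whole
#' session, plus stimulus-driven spikes at the [rate_model()] driven rate
#' (constant within each epoch). Laser-on and laser-off epochs alternate
#' throughout the session.
#'
#' Negative model rates (possible only for pathological parameters) are
#' clamped to zero with a warning.
#'
#' @param config A [sim_config()].
#' @param units Ground-truth table from [make_units()]; defaults to
#'   generating one from `config`.
#' @return A list of class `"tg_session"`: `epochs` (one row per stimulus
#'   presentation), `spikes` (columns `unit_id`, `area`, `depth_rank`,
#'   `spike_time_s`, sorted within unit), `units` (the ground truth), and
#'   `config`.
#' @export
#' @examples
#' s <- simulate_session(sim_config(seed = 1, n_units = c(dLGN = 2),
#'                                  n_trials = 2))
#' head(s$spikes)
simulate_session <- function(config, units = make_units(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  epochs <- tg_make_epochs(config)
  t_end <- max(epochs$onset_s + epochs$duration_s) + config$isi_s
  spikes <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    driven <- rate_model(u, epochs) - u$spont_hz
    if (any(driven < -1e-9)) {
      warning("negative model rate clamped to 0 for unit ", u$unit_id)
    }
    driven <- pmax(driven, 0)
    # background spontaneous spikes over the whole session
    n_bg <- rpois(1L, u$spont_hz * t_end)
    t_bg <- runif(n_bg, 0, t_end)
    # driven spikes, piecewise-constant rate within epochs
    n_ep <- rpois(nrow(epochs), driven * epochs$duration_s)
    t_ep <- rep(epochs$onset_s, n_ep) +
      runif(sum(n_ep), 0, rep(epochs$duration_s, n_ep))
    st <- sort(c(t_bg, t_ep))
    spikes[[i]] <- data.frame(unit_id = u$unit_id, area = u$area,
                              depth_rank = u$depth_rank,
                              spike_time_s = st,
                              stringsAsFactors = FALSE)
  }
  structure(list(epochs = epochs,
                 spikes = do.call(rbind, spikes),
                 units = units,
                 config = config),
            class = "tg_session")
}

#' Simulate per-trial evoked responses at the count level
#'
#' Fast path for simulation studies: instead of materialising spike times,
#' draws the stimulus-window and spontaneous-window Poisson counts directly
#' and returns the evoked response each trial would yield,
#' `count_stim / dur - count_spont / 0.5`. This is distributionally
#' identical to running [simulate_session()] followed by
#' [trial_responses()], at a fraction of the cost, and is what the
#' repeated-simulation calibration studies use.
#'
#' @param config A [sim_config()].
#' @param units Ground-truth table.
#' @param sizes_deg,contrasts_pct Condition grids; default to the size
#'   series at the grating contrast. Supplying several contrasts crosses
#'   them fully with the sizes (used by the contrast-matching analyses).
#' @param n_trials Trials per condition and laser state.
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return Data.frame with one row per unit x size x direction x contrast x
#'   laser x trial and column `evoked_hz`.
#' @export
simulate_trial_counts <- function(config, units,
                                  sizes_deg = config$sizes_deg,
                                  contrasts_pct = config$grating_contrast_pct,
                                  n_trials = config$n_trials,
                                  seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  grid <- expand.grid(size_deg = sizes_deg,
                      direction_deg = config$directions_deg,
                      contrast_pct = contrasts_pct,
                      laser_on = c(FALSE, TRUE))
  dur <- config$stimulus_duration_s
  out <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    rate <- rate_model(u, grid)
    ntot <- nrow(grid) * n_trials
    rate_rep <- rep(rate, each = n_trials)
    stim <- rpois(ntot, rate_rep * dur) / dur
    spont <- rpois(ntot, u$spont_hz * 0.5) / 0.5
    df <- grid[rep(seq_len(nrow(grid)), each = n_trials), , drop = FALSE]
    df$trial <- rep(seq_len(n_trials), times = nrow(grid))
    df$unit_id <- u$unit_id
    df$area <- u$area
    df$evoked_hz <- stim - spont
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a sparse-noise receptive-field mapping session
#'
#' Emulates a movie of small white squares at random positions on a black
#' background (white:black area ratio about 1:30). Each frame lights a
#' fixed number of grid cells; a unit fires above its spontaneous rate,
#' after a fixed response latency, when a lit square falls near its
#' receptive-field centre (Gaussian spatial weighting).
#'
#' @param config A [sim_config()]; the movie uses `sn_duration_s`,
#'   `sn_fps`, `sn_square_deg` and the screen extent.
#' @param units Ground-truth table.
#' @param rf_sigma_deg Spatial standard deviation of the RF weighting.
#' @param latency_s Response latency (seconds).
#' @return A list of class `"tg_sparse_noise"`: `frames` (list with the
#'   cell-centre grids `az`, `el`, integer matrix `lit` of lit-cell indices
#'   per frame, `onset_s`, `frame_duration_s`), and `spikes` (as in
#'   [simulate_session()]).
#' @export
simulate_sparse_noise <- function(config, units, rf_sigma_deg = 4,
                                  latency_s = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  sq <- config$sn_square_deg
  az <- seq(config$screen_az_deg[1] + sq / 2, config$screen_az_deg[2], by = sq)
  el <- seq(config$screen_el_deg[1] + sq / 2, config$screen_el_deg[2], by = sq)
  n_cells <- length(az) * length(el)
  n_frames <- round(config$sn_duration_s * config$sn_fps)
  n_lit <- max(1L, round(n_cells / 31))  # white:black about 1:30
  lit <- t(vapply(seq_len(n_frames),
                  function(f) sample.int(n_cells, n_lit),
                  integer(n_lit)))
  frame_dur <- 1 / config$sn_fps
  onset <- (seq_len(n_frames) - 1L) * frame_dur
  cell_az <- rep(az, times = length(el))
  cell_el <- rep(el, each = length(az))
  if (any(units$rf_az_deg < config$screen_az_deg[1] |
          units$rf_az_deg > config$screen_az_deg[2] |
          units$rf_el_deg < config$screen_el_deg[1] |
          units$rf_el_deg > config$screen_el_deg[2]))
    stop("unit RF centre outside the screen extent")
  spikes <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    d2 <- (cell_az - u$rf_az_deg)^2 + (cell_el - u$rf_el_deg)^2
    w <- exp(-d2 / (2 * rf_sigma_deg^2))
    # drive per frame: strongest lit square wins
    drive <- apply(lit, 1L, function(idx) max(w[idx]))
    rate <- u$spont_hz + u$peak_rate_hz * drive
    n <- rpois(n_frames, rate * frame_dur)
    st <- rep(onset, n) + runif(sum(n), 0, frame_dur) + latency_s
    spikes[[i]] <- data.frame(unit_id = u$unit_id, area = u$area,
                              depth_rank = u$depth_rank,
                              spike_time_s = sort(st),
                              stringsAsFactors = FALSE)
  }
  structure(list(frames = list(az = az, el = el, cell_az = cell_az,
                               cell_el = cell_el, lit = lit,
                               onset_s = onset,
                               frame_duration_s = frame_dur),
                 spikes = do.call(rbind, spikes),
                 units = units,
                 latency_s = latency_s),
            class = "tg_sparse_noise")
}

# Biphasic extracellular spike waveform template, negative trough first,
# normalized to a trough of -1. Length about 1.2 ms at the given rate.
tg_waveform <- function(sampling_rate_hz) {
  t <- seq(0, 0.0012, by = 1 / sampling_rate_hz)
  w <- -exp(-((t - 2e-4) / 1.2e-4)^2) + 0.35 * exp(-((t - 5.5e-4) / 2.5e-4)^2)
  w / abs(min(w))
}

#' Synthesise a filtered voltage trace from spike times
#'
#' Produces Gaussian background noise with a biphasic (negative-first)
#' spike waveform added at each spike time, amplitude expressed in
#' multiples of the noise standard deviation. This closes the loop with
#' [detect_spikes()]: detection recall on known insertion times can be
#' measured directly.
#'
#' @param spike_times_s Spike times (seconds).
#' @param duration_s Trace length (seconds).
#' @param sampling_rate_hz Sampling rate; must be at least 20 kHz
#'   (defaults to 24 kHz).
#' @param noise_sd Background noise standard deviation (arbitrary units).
#' @param amplitude_sd Trough amplitude in multiples of `noise_sd`.
#' @param seed Optional seed for the noise.
#' @return A list of class `"tg_trace"`: `samples`, `sampling_rate_hz`,
#'   `spike_times_s`, and `n_collisions` (pairs of spikes closer than one
#'   waveform length; their waveforms are overlap-added).
#' @export
simulate_voltage <- function(spike_times_s, duration_s,
                             sampling_rate_hz = 24000,
                             noise_sd = 1, amplitude_sd = 6,
                             seed = NULL) {
  if (sampling_rate_hz < 20000)
    stop("sampling_rate_hz must be >= 20000")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate_hz)
  x <- rnorm(n, 0, noise_sd)
  w <- tg_waveform(sampling_rate_hz) * amplitude_sd * noise_sd
  st <- sort(spike_times_s)
  st <- st[st >= 0 & st < duration_s - length(w) / sampling_rate_hz]
  idx <- round(st * sampling_rate_hz) + 1L
  for (i0 in idx) {
    j <- i0:(i0 + length(w) - 1L)
    x[j] <- x[j] + w
  }
  n_coll <- sum(diff(st) < length(w) / sampling_rate_hz)
  structure(list(samples = x, sampling_rate_hz = sampling_rate_hz,
                 spike_times_s = st, n_collisions = n_coll),
            class = "tg_trace")
}
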