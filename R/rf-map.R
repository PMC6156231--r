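#' Receptive-field estimate by spike-triggered averaging
#'
#' Averages the sparse-noise frames active one response latency before
#' each spike. The receptive-field centre is the screen position of the
#' STA peak; its significance score is a permutation z-score of the peak
#' against circularly time-shifted spike trains (which preserve the spike
#' train's internal structure while breaking its alignment to the
#' stimulus).
#'
#' @param spike_times_s Spike times of one unit (seconds).
#' @param frames Frame description as produced by
#'   [simulate_sparse_noise()]: list with cell centres `cell_az`,
#'   `cell_el`, lit-cell index matrix `lit`, `onset_s` and
#'   `frame_duration_s`.
#' @param latency_s Response latency subtracted from each spike time
#'   before frame lookup (default 50 ms).
#' @param n_perm Number of circular-shift permutations for the score.
#' @param seed Seed for the permutation shifts.
#' @return List of class `"rf_estimate"`: `center` (named vector
#'   `az`, `el`, degrees), `score` (permutation z of the STA peak), `sta`
#'   (per-cell STA values), and `n_spikes`.
#' @export
rf_map <- function(spike_times_s, frames, latency_s = 0.05,
                   n_perm = 100L, seed = 1L) {
  if (length(spike_times_s) == 0L) stop("no spikes; RF undefined")
  n_frames <- nrow(frames$lit)
  t_total <- n_frames * frames$frame_duration_s
  sta_counts <- function(st) {
    fi <- findInterval(st - latency_s, frames$onset_s)
    fi <- fi[fi >= 1 & fi <= n_frames]
    if (length(fi) == 0L) return(NULL)
    # accumulate spike counts over the lit cells of each triggering frame
    idx <- as.vector(t(frames$lit[fi, , drop = FALSE]))
    tab <- tabulate(idx, nbins = length(frames$cell_az))
    tab / length(fi)
  }
  obs <- sta_counts(spike_times_s)
  if (is.null(obs)) stop("no spikes fall within the frame sequence")
  peak <- max(obs)
  ipk <- which.max(obs)
  set.seed(seed)
  shifts <- runif(n_perm, 0.05 * t_total, 0.95 * t_total)
  perm_peaks <- vapply(shifts, function(dt) {
    st <- (spike_times_s - latency_s + dt) %% t_total + latency_s
    max(sta_counts(sort(st)))
  }, numeric(1))
  score <- (peak - mean(perm_peaks)) /
    max(sd(perm_peaks), .Machine$double.eps)
  structure(list(center = c(az = frames$cell_az[ipk],
                            el = frames$cell_el[ipk]),
                 score = score,
                 sta = obs,
                 n_spikes = length(spike_times_s)),
            class = "rf_estimate")
}
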