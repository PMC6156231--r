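#' Simulation configuration
#'
#' Bundles the stimulus protocol and cohort layout used by the synthetic
#' session generator. Defaults reproduce the recording protocol the analysis
#' pipeline targets: drifting-grating disks of 10--120 degrees diameter in 12
#' directions at 95% contrast, 1 s on / 1 s off, 10 interleaved repetitions
#' per condition with the laser on in every other trial, plus a 5-minute
#' sparse-noise movie at 5 frames per second for receptive-field mapping and
#' a 7-point contrast series at a fixed near-optimal size.
#'
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_units Named integer vector of cohort sizes per area. Names must
#'   be a subset of `c("sSC","dLGN","LP","PBG","V1")`.
#' @param n_trials Repetitions per stimulus condition and laser state.
#' @param sizes_deg Grating disk diameters (visual degrees).
#' @param directions_deg Drift directions (degrees, uniform grid on
#'   `[0,360)`).
#' @param contrasts_pct Contrast levels (percent) for the contrast series.
#' @param grating_contrast_pct Contrast of the size-tuning series.
#' @param contrast_size_deg Disk size at which the contrast series is run
#'   (fixed, chosen near the population optimum).
#' @param stimulus_duration_s,isi_s Stimulus-on and interstimulus durations
#'   in seconds. The interstimulus interval must leave at least 0.5 s for
#'   the spontaneous window preceding each onset.
#' @param sn_duration_s,sn_fps,sn_square_deg Sparse-noise movie length,
#'   frame rate, and square width.
#' @param screen_az_deg,screen_el_deg Screen extent, degrees, as
#'   `c(min, max)`.
#'
#' @return An object of class `"sim_config"` (a named list).
#' @seealso [make_units()], [simulate_session()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_units = c(V1 = 5))
#' cfg$sizes_deg
sim_config <- function(seed = 1L,
                       n_units = c(sSC = 40L, dLGN = 26L, LP = 12L,
                                   PBG = 12L, V1 = 150L),
                       n_trials = 10L,
                       sizes_deg = c(10, 25, 40, 60, 90, 120),
                       directions_deg = seq(0, 330, by = 30),
                       contrasts_pct = c(5, 20, 35, 50, 65, 80, 95),
                       grating_contrast_pct = 95,
                       contrast_size_deg = 40,
                       stimulus_duration_s = 1,
                       isi_s = 1,
                       sn_duration_s = 300,
                       sn_fps = 5,
                       sn_square_deg = 5,
                       screen_az_deg = c(-60, 60),
                       screen_el_deg = c(-40, 40)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (length(n_units) == 0L || is.null(names(n_units)))
    stop("`n_units` must be a named vector of per-area cohort sizes")
  bad <- setdiff(names(n_units), TG_AREAS)
  if (length(bad))
    stop("unknown area(s) in `n_units`: ", paste(bad, collapse = ", "))
  if (any(n_units < 0)) stop("`n_units` must be non-negative")
  for (nm in c("sizes_deg", "directions_deg", "contrasts_pct")) {
    v <- get(nm)
    if (length(v) == 0L) stop("`", nm, "` must be non-empty")
  }
  if (any(contrasts_pct <= 0 | contrasts_pct > 100))
    stop("`contrasts_pct` must lie in (0, 100]")
  if (stimulus_duration_s <= 0) stop("`stimulus_duration_s` must be > 0")
  if (isi_s < 0.5)
    stop("`isi_s` must be >= 0.5 s so the spontaneous window fits ",
         "between stimuli")
  structure(
    list(seed = as.integer(seed),
         n_units = n_units,
         n_trials = as.integer(n_trials),
         sizes_deg = sort(sizes_deg),
         directions_deg = sort(directions_deg %% 360),
         contrasts_pct = sort(contrasts_pct),
         grating_contrast_pct = grating_contrast_pct,
         contrast_size_deg = contrast_size_deg,
         stimulus_duration_s = stimulus_duration_s,
         isi_s = isi_s,
         sn_duration_s = sn_duration_s,
         sn_fps = sn_fps,
         sn_square_deg = sn_square_deg,
         screen_az_deg = screen_az_deg,
         screen_el_deg = screen_el_deg),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  units:", paste(names(x$n_units), x$n_units, sep = "=",
                        collapse = ", "), "\n")
  cat("  sizes (deg):", paste(x$sizes_deg, collapse = ", "), "\n")
  cat("  directions (deg):", paste(x$directions_deg, collapse = ", "), "\n")
  cat("  contrasts (%):", paste(x$contrasts_pct, collapse = ", "), "\n")
  cat("  trials/condition:", x$n_trials, "\n")
  invisible(x)
}
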