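# Cohort-level size x laser analyses shared by the pipeline, the
# simulation studies and the tests.

#' Per-unit direction-averaged size-tuning curves from trial data
#'
#' Collapses a trial-level evoked-response table to one direction-averaged
#' mean response per unit, size and laser state (at a single contrast),
#' in the paired wide format used by [ssi_change_analysis()] and
#' [shape_interaction_test()].
#'
#' @param trials Data.frame with `unit_id`, `size_deg`, `direction_deg`,
#'   `laser_on`, `evoked_hz` (and optionally `contrast_pct`).
#' @param contrast_pct Contrast to select; defaults to the maximum
#'   present.
#' @return Data.frame with `unit_id`, `size_deg`, `R_off`, `R_on`.
#' @export
unit_size_curves <- function(trials, contrast_pct = NULL) {
  if ("contrast_pct" %in% names(trials)) {
    if (is.null(contrast_pct)) contrast_pct <- max(trials$contrast_pct)
    trials <- trials[trials$contrast_pct == contrast_pct, , drop = FALSE]
  }
  # mean per (unit, size, direction, laser), then mean over directions
  cell <- aggregate(trials["evoked_hz"],
                    trials[c("unit_id", "size_deg", "direction_deg",
                             "laser_on")], mean)
  da <- aggregate(cell["evoked_hz"],
                  cell[c("unit_id", "size_deg", "laser_on")], mean)
  off <- da[!da$laser_on, c("unit_id", "size_deg", "evoked_hz")]
  on <- da[da$laser_on, c("unit_id", "size_deg", "evoked_hz")]
  names(off)[3] <- "R_off"; names(on)[3] <- "R_on"
  out <- merge(off, on, by = c("unit_id", "size_deg"))
  out <- out[order(out$unit_id, out$size_deg), ]
  rownames(out) <- NULL
  out
}

#' Does a manipulation change the shape of size tuning?
#'
#' Two-way ANOVA interaction (laser x size step) on per-unit size-tuning
#' curves that are first aligned on each unit's laser-off optimum and then
#' normalised, within each laser state, by that state's response at the
#' laser-off preferred size. Under a pure multiplicative gain change the
#' normalised laser-on and laser-off curves coincide, so the interaction
#' null holds exactly and the test rejects at its nominal level; a
#' size-dependent (shape) change produces a real interaction.
#'
#' Units whose response at the preferred size is not positive in both
#' laser states are dropped (normalisation undefined).
#'
#' @param curves Data.frame as from [unit_size_curves()]: `unit_id`,
#'   `size_deg`, `R_off`, `R_on`.
#' @return As [interaction_test()], plus `n_units`.
#' @export
shape_interaction_test <- function(curves) {
  ids <- unique(curves$unit_id)
  rows <- lapply(ids, function(id) {
    cu <- curves[curves$unit_id == id, , drop = FALSE]
    cu <- cu[order(cu$size_deg), ]
    pref <- preferred_size(cu$size_deg, cu$R_off)
    ip <- match(pref, cu$size_deg)
    if (cu$R_off[ip] <= 0 || cu$R_on[ip] <= 0) return(NULL)
    step <- seq_len(nrow(cu)) - ip
    rbind(data.frame(unit_id = id, laser_on = FALSE, step = step,
                     norm_R = cu$R_off / cu$R_off[ip]),
          data.frame(unit_id = id, laser_on = TRUE, step = step,
                     norm_R = cu$R_on / cu$R_on[ip]))
  })
  norm <- do.call(rbind, rows)
  if (is.null(norm) || length(unique(norm$unit_id)) < 3L)
    stop("need at least 3 units with positive preferred-size responses")
  # units with different optima cover different step ranges; keep steps
  # represented by at least two units so every ANOVA cell is populated
  nstep <- table(norm$step[!norm$laser_on])
  keep <- as.integer(names(nstep)[nstep >= 2L])
  norm <- norm[norm$step %in% keep, , drop = FALSE]
  res <- interaction_test(norm, response = "norm_R",
                          f1 = "laser_on", f2 = "step")
  res$n_units <- length(unique(norm$unit_id))
  res
}
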