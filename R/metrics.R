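# Tuning indices and derived summaries.

#' Surround suppression index
#'
#' `SSI = (R_pref - R_large) / R_pref`, where `R_pref` is the
#' direction-averaged response at the preferred size and `R_large` the
#' response at the largest presented size. A negative `R_large` is floored
#' at 0 so the index stays in `[0, 1]`; `R_pref` must be positive (units
#' failing the inclusion criterion are excluded upstream).
#'
#' Note that the SSI of two cohort-mean rates is not the cohort mean of
#' per-unit SSIs; both are meaningful but different summaries.
#'
#' @param r_pref,r_large Responses in Hz (vectorised).
#' @return SSI in `[0, 1]`.
#' @export
#' @examples
#' ssi(10, 5)        # 0.5
#' ssi(30.5, 20.0)   # SSI of cohort-mean rates
ssi <- function(r_pref, r_large) {
  if (any(r_pref <= 0))
    stop("ssi undefined for r_pref <= 0; unit should have been excluded")
  (r_pref - pmax(r_large, 0)) / r_pref
}

# Resultant length of responses over angles (degrees), with the angle
# multiplied by `fold`. Negative responses are floored at 0; an all-zero
# vector is an error.
tg_resultant <- function(directions_deg, responses, fold) {
  stopifnot(length(directions_deg) == length(responses))
  r <- pmax(responses, 0)
  tot <- sum(r)
  if (tot <= 0) stop("all responses zero or negative; index undefined")
  phi <- fold * directions_deg * pi / 180
  sqrt(sum(r * sin(phi))^2 + sum(r * cos(phi))^2) / tot
}

#' Orientation selectivity index (1 - circular variance)
#'
#' `OSI = sqrt((sum R sin 2phi)^2 + (sum R cos 2phi)^2) / sum R`: the
#' length of the resultant vector of the responses at doubled direction
#' angles, normalised by the summed response. Equal to one minus the
#' circular variance of the doubled-angle response distribution.
#'
#' @param directions_deg Stimulus directions (degrees, uniform grid over
#'   the full circle).
#' @param responses Mean responses per direction (Hz); negatives floored
#'   at 0.
#' @return OSI in `[0, 1]`.
#' @export
#' @examples
#' osi(c(0, 90, 180, 270), c(1, 0, 1, 0))  # 1: perfectly orientation tuned
osi <- function(directions_deg, responses) {
  tg_resultant(directions_deg, responses, fold = 2)
}

#' Direction selectivity index
#'
#' As [osi()] but with single (unfolded) angles:
#' `DSI = sqrt((sum R sin phi)^2 + (sum R cos phi)^2) / sum R`.
#'
#' @inheritParams osi
#' @return DSI in `[0, 1]`.
#' @export
#' @examples
#' dsi(c(0, 90, 180, 270), c(2, 0, 1, 0))  # 1/3
dsi <- function(directions_deg, responses) {
  tg_resultant(directions_deg, responses, fold = 1)
}

#' Percent response reduction
#'
#' `100 * (r_off - r_on) / r_off`, rounded to the nearest integer percent
#' by default (set `digits = NULL` for the unrounded value). Undefined for
#' non-positive baseline.
#'
#' @param r_off,r_on Responses without / with the manipulation (Hz).
#' @param digits Rounding digits; `NULL` for none.
#' @return Percent reduction (vectorised).
#' @export
#' @examples
#' percent_reduction(17.4, 11.6)  # 33
percent_reduction <- function(r_off, r_on, digits = 0) {
  if (any(r_off <= 0)) stop("percent_reduction undefined for r_off <= 0")
  out <- 100 * (r_off - r_on) / r_off
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Fraction as nearest-integer percent
#'
#' Helper for reporting count fractions (e.g. an upper bound of 1 labelled
#' cell out of 28) as integer percentages.
#'
#' @param k,n Numerator and denominator counts.
#' @return `round(100 * k / n)`.
#' @export
#' @examples
#' fraction_to_percent(1, 28)  # 4
fraction_to_percent <- function(k, n) {
  stopifnot(n > 0, k >= 0)
  round(100 * k / n)
}

#' Preferred size of a size-tuning curve
#'
#' The size with the maximal response; ties are broken towards the
#' smallest size.
#'
#' @param sizes_deg Sizes (degrees).
#' @param R Responses (Hz), same length.
#' @return The preferred size (degrees).
#' @export
preferred_size <- function(sizes_deg, R) {
  stopifnot(length(sizes_deg) == length(R), length(R) >= 1L)
  o <- order(sizes_deg)
  sizes_deg <- sizes_deg[o]; R <- R[o]
  sizes_deg[which.max(R)]  # which.max returns the first (smallest) maximum
}

#' Align a size-tuning curve on its optimum
#'
#' Re-indexes a tuning curve by size step relative to the unit's preferred
#' size: step 0 at the optimum, negative steps for smaller presented
#' sizes, positive for larger, in presented-size rank units. Population
#' curves average units on the step axis.
#'
#' @param sizes_deg,R Size-tuning curve.
#' @param pref_size_deg Optional externally determined preferred size
#'   (e.g. from the laser-off curve when aligning the laser-on curve).
#' @return Data.frame with `step`, `size_deg`, `R`.
#' @export
#' @examples
#' align_to_optimal(c(10, 25, 40, 60), c(3, 8, 5, 2))
align_to_optimal <- function(sizes_deg, R, pref_size_deg = NULL) {
  stopifnot(length(sizes_deg) >= 2L, length(sizes_deg) == length(R))
  o <- order(sizes_deg)
  sizes_deg <- sizes_deg[o]; R <- R[o]
  if (is.null(pref_size_deg)) pref_size_deg <- preferred_size(sizes_deg, R)
  i0 <- match(pref_size_deg, sizes_deg)
  if (is.na(i0)) stop("pref_size_deg is not one of the presented sizes")
  data.frame(step = seq_along(sizes_deg) - i0, size_deg = sizes_deg, R = R)
}

#' Population average of optimum-aligned curves
#'
#' @param aligned List of [align_to_optimal()] results (one per unit).
#' @return Data.frame with `step`, `mean_R`, `sem_R`, `n`.
#' @export
population_align <- function(aligned) {
  all <- do.call(rbind, aligned)
  sp <- split(all$R, all$step)
  data.frame(step = as.integer(names(sp)),
             mean_R = vapply(sp, mean, numeric(1)),
             sem_R = vapply(sp, function(x) sd(x) / sqrt(length(x)),
                            numeric(1)),
             n = vapply(sp, length, numeric(1)),
             row.names = NULL)
}

#' Multiplicative gain between paired tuning curves
#'
#' Least-squares slope through the origin of laser-on versus laser-off
#' responses across condition cells: the fitted single multiplicative
#' factor on the driven component. Recovers the generator's `laser_gain`
#' for areas where the manipulation is a pure gain change.
#'
#' @param r_off,r_on Paired responses (Hz) across conditions.
#' @return Estimated gain (dimensionless).
#' @export
gain_estimate <- function(r_off, r_on) {
  stopifnot(length(r_off) == length(r_on))
  den <- sum(r_off^2)
  if (den <= 0) stop("gain undefined: no laser-off signal")
  sum(r_on * r_off) / den
}

#' Per-unit surround-suppression change under a paired manipulation
#'
#' Computes SSI without and with the manipulation for every unit, using
#' the laser-off curve to fix the preferred size for both states (the
#' comparison stays paired), and reports the change. Units that are not
#' surround suppressed at baseline (`SSI = 0`) are excluded by default,
#' because a response change cannot register as an SSI change in an
#' unsuppressed unit.
#'
#' @param curves Data.frame with one row per unit x size: `unit_id`,
#'   `size_deg`, `R_off`, `R_on` (direction-averaged evoked responses,
#'   Hz).
#' @param exclude_zero Drop units with `SSI_off == 0` (default `TRUE`).
#' @return Data.frame with `unit_id`, `ssi_off`, `ssi_on`, `delta_ssi`,
#'   `pct_reduction`. Units whose baseline preferred response is not
#'   positive are dropped (they fail inclusion upstream anyway).
#' @export
ssi_change_analysis <- function(curves, exclude_zero = TRUE) {
  need <- c("unit_id", "size_deg", "R_off", "R_on")
  miss <- setdiff(need, names(curves))
  if (length(miss))
    stop("curves lack column(s): ", paste(miss, collapse = ", "))
  ids <- unique(curves$unit_id)
  rows <- lapply(ids, function(id) {
    cu <- curves[curves$unit_id == id, , drop = FALSE]
    cu <- cu[order(cu$size_deg), ]
    pref <- preferred_size(cu$size_deg, cu$R_off)
    ip <- match(pref, cu$size_deg)
    il <- nrow(cu)
    if (cu$R_off[ip] <= 0) return(NULL)
    s_off <- ssi(cu$R_off[ip], cu$R_off[il])
    s_on <- if (cu$R_on[ip] > 0) ssi(cu$R_on[ip], cu$R_on[il]) else NA_real_
    data.frame(unit_id = id, ssi_off = s_off, ssi_on = s_on,
               delta_ssi = s_on - s_off,
               pct_reduction = if (s_off > 0)
                 100 * (s_off - s_on) / s_off else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(unit_id = character(), ssi_off = numeric(),
                      ssi_on = numeric(), delta_ssi = numeric(),
                      pct_reduction = numeric()))
  if (exclude_zero) out <- out[out$ssi_off > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast-matching between an optogenetic and a contrast manipulation
#'
#' Implements the two-step matching procedure on a pair of contrast
#' response curves at fixed (optimal) size: find the highest contrast at
#' which the laser causes roughly a 15% response reduction (within
#' `tol_pct` percentage points), then pick the lower contrast whose
#' laser-off response best matches the laser-on response at that high
#' contrast.
#'
#' @param contrasts_pct Contrast grid (percent).
#' @param r_off,r_on Laser-off / laser-on responses on that grid (Hz).
#' @param target_pct Target reduction (default 15).
#' @param tol_pct Acceptance band around the target (default +/- 5
#'   percentage points).
#' @return List with `high_contrast_pct`, `lower_contrast_pct`,
#'   `reduction_pct` (reduction at the high contrast) and
#'   `match_error_hz` (absolute response mismatch at the chosen lower
#'   contrast). Errors with class `"tg_no_contrast_match"` if no grid
#'   contrast shows the target reduction (e.g. no laser effect).
#' @export
#' @examples
#' cc <- c(5, 20, 35, 50, 65, 80, 95)
#' r0 <- 30 * cc / (cc + 30)
#' contrast_match(cc, r0, 0.85 * r0)
contrast_match <- function(contrasts_pct, r_off, r_on,
                           target_pct = 15, tol_pct = 5) {
  stopifnot(length(contrasts_pct) == length(r_off),
            length(r_off) == length(r_on))
  o <- order(contrasts_pct)
  contrasts_pct <- contrasts_pct[o]; r_off <- r_off[o]; r_on <- r_on[o]
  ok <- r_off > 0
  red <- rep(NA_real_, length(r_off))
  red[ok] <- 100 * (r_off[ok] - r_on[ok]) / r_off[ok]
  eligible <- which(ok & abs(red - target_pct) <= tol_pct)
  if (length(eligible) == 0L)
    stop(structure(class = c("tg_no_contrast_match", "error", "condition"),
                   list(message = paste0(
                     "no contrast with a reduction within ", target_pct,
                     " +/- ", tol_pct, "% (is there a laser effect?)"),
                     call = sys.call())))
  hi <- max(eligible)
  r_target <- r_on[hi]
  err <- abs(r_off - r_target)
  lo <- which(err == min(err))[1L]  # ties: lowest contrast
  list(high_contrast_pct = contrasts_pct[hi],
       lower_contrast_pct = contrasts_pct[lo],
       reduction_pct = red[hi],
       match_error_hz = err[lo])
}
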