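# Firing-rate model.
#
# Subcortical areas (sSC, dLGN, LP, PBG):
#   rate = spont + g_laser * C(contrast) * D(direction) * peak * S(size)
# with S a ratio-of-Gaussians spatial-summation profile (normalized to 1 at
# the unit's preferred size), C a saturating hyperbolic contrast term
# (normalized to 1 at 95% contrast) and D a direction profile with unit
# value at the preferred direction. The laser multiplies the driven term
# only; spontaneous rate is untouched.
#
# V1: the geniculate drive d = C * Lc(size) (scaled by the laser gain g that
# reaches cortex through the geniculate relay) passes through divisive
# normalization,
#   resp = d*g / (sigma + d*g + C * w * Ls(size) * g),
# so a uniform g < 1 removes proportionally more response at the optimum
# (where the semisaturation constant sigma dominates the denominator) than
# at the largest sizes (where the normalization pool dominates). Lowering
# contrast acts through the identical C*g product, which is what makes a
# contrast reduction and a gain reduction indistinguishable in V1.

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Integrated Gaussian drive of a stimulus of diameter s (degrees) over a
# mechanism of width w: the classic saturating erf^2 form.
tg_lsum <- function(s, w) erf(s / w)^2

# Direction profile, 1 at the preferred direction. With osi = o, dsi = d the
# profile 1 + 2d cos(dphi) + 2o cos(2 dphi) (before peak normalization) has,
# on any uniform full-circle grid, selectivity indices exactly o and d,
# provided it is non-negative; make_units rescales (o, d) to guarantee that.
tg_dir_profile <- function(dphi_deg, osi, dsi) {
  dphi <- dphi_deg * pi / 180
  raw <- 1 + 2 * dsi * cos(dphi) + 2 * osi * cos(2 * dphi)
  pmax(raw, 0) / (1 + 2 * dsi + 2 * osi)
}

# Contrast term, 1 at 95% contrast.
tg_contrast_term <- function(contrast_pct, c50) {
  (contrast_pct / (contrast_pct + c50)) / (95 / (95 + c50))
}

# Size response before direction/contrast/laser factors, NOT normalized.
# Subcortical: ratio of Gaussians. V1: normalization expression evaluated at
# full contrast and gain 1 (the gain/contrast enter jointly elsewhere).
tg_size_response <- function(unit, sizes_deg, cg = 1) {
  lc <- tg_lsum(sizes_deg, unit$size_wc_deg)
  ls <- tg_lsum(sizes_deg, unit$size_ws_deg)
  if (unit$area == "V1") {
    d <- cg * lc
    pool <- cg * unit$suppression_strength * ls
    d / (unit$norm_sigma + d + pool)
  } else {
    lc / (1 + unit$suppression_strength * ls)
  }
}

# Peak-normalization constant: driven rate equals peak_rate_hz at the
# preferred size, preferred direction, 95% contrast, laser off.
tg_peak_norm <- function(unit) {
  unit$peak_rate_hz / tg_size_response(unit, unit$pref_size_deg)
}

#' Expected firing rate of a model unit for given stimulus epochs
#'
#' Evaluates the noiseless rate model for one ground-truth unit over a set
#' of grating epochs. Subcortical units follow spontaneous + gain x
#' contrast x direction x ratio-of-Gaussians size tuning; V1 units follow a
#' divisive-normalization stage driven by the (gain-scaled) geniculate
#' drive, so the same multiplicative gain produces a size-dependent effect
#' in V1 but a size-independent one elsewhere.
#'
#' The laser multiplies the stimulus-driven component only; the spontaneous
#' rate is unaffected.
#'
#' @param unit One row of a [make_units()] table (data.frame or list).
#' @param epochs Data.frame with columns `size_deg`, `direction_deg`,
#'   `contrast_pct`, `laser_on`.
#' @return Numeric vector of expected rates (Hz), one per epoch, floored
#'   at zero.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_units = c(dLGN = 1))
#' u <- make_units(cfg)
#' ep <- data.frame(size_deg = u$pref_size_deg, direction_deg = u$pref_dir_deg,
#'                  contrast_pct = 95, laser_on = FALSE)
#' rate_model(u, ep) - u$spont_hz  # equals u$peak_rate_hz
rate_model <- function(unit, epochs) {
  if (is.data.frame(unit)) {
    stopifnot(nrow(unit) == 1L)
    unit <- as.list(unit)
  }
  if (!unit$area %in% TG_AREAS)
    stop("unknown area: ", unit$area)
  need <- c("size_deg", "direction_deg", "contrast_pct", "laser_on")
  miss <- setdiff(need, names(epochs))
  if (length(miss))
    stop("epochs lack column(s): ", paste(miss, collapse = ", "))
  g <- ifelse(epochs$laser_on, unit$laser_gain, 1)
  cg <- tg_contrast_term(epochs$contrast_pct, unit$contrast_c50)
  dirf <- tg_dir_profile(epochs$direction_deg - unit$pref_dir_deg,
                         unit$osi_true, unit$dsi_true)
  if (unit$area == "V1") {
    lc <- tg_lsum(epochs$size_deg, unit$size_wc_deg)
    ls <- tg_lsum(epochs$size_deg, unit$size_ws_deg)
    d <- cg * lc * g
    pool <- cg * unit$suppression_strength * ls * g
    driven <- tg_peak_norm(unit) * dirf * d / (unit$norm_sigma + d + pool)
  } else {
    driven <- tg_peak_norm(unit) * dirf * g * cg *
      tg_size_response(unit, epochs$size_deg)
  }
  pmax(unit$spont_hz + driven, 0)
}

#' Noiseless direction-averaged size-tuning curve of a model unit
#'
#' Evoked (spontaneous-subtracted) expected response per size, averaged
#' over a uniform direction grid, as the analysis pipeline would recover it
#' with unlimited trials. Used for ground-truth SSI and for the
#' gain-invariance properties of the generator.
#'
#' @param unit One ground-truth unit row.
#' @param sizes_deg Sizes at which to evaluate (degrees).
#' @param contrast_pct Contrast (percent).
#' @param laser_on Logical; apply the unit's laser gain.
#' @return Numeric vector of driven rates (Hz) per size.
#' @export
model_size_tuning <- function(unit, sizes_deg, contrast_pct = 95,
                              laser_on = FALSE) {
  if (is.data.frame(unit)) unit <- as.list(unit)
  g <- if (isTRUE(laser_on)) unit$laser_gain else 1
  cg <- tg_contrast_term(contrast_pct, unit$contrast_c50)
  dir_mean <- 1 / (1 + 2 * unit$dsi_true + 2 * unit$osi_true)
  if (unit$area == "V1") {
    lc <- tg_lsum(sizes_deg, unit$size_wc_deg)
    ls <- tg_lsum(sizes_deg, unit$size_ws_deg)
    d <- cg * lc * g
    pool <- cg * unit$suppression_strength * ls * g
    tg_peak_norm(unit) * dir_mean * d / (unit$norm_sigma + d + pool)
  } else {
    tg_peak_norm(unit) * dir_mean * g * cg *
      tg_size_response(unit, sizes_deg)
  }
}
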