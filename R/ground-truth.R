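# Ground-truth cohort generator.
#
# Each simulated unit carries the true parameters of its firing-rate model
# so that downstream estimates (SSI, OSI/DSI, RF centre, laser gain) can be
# checked against them. Subcortical units (sSC, dLGN, LP, PBG) follow a
# ratio-of-Gaussians size-tuning profile with a saturating contrast term;
# V1 units are driven by a geniculate drive passed through divisive
# normalization, so that a uniform geniculate gain drop has a
# size-dependent cortical effect.

# Per-area default parameters. Mean driven rates, spontaneous rates and
# laser gains mirror the magnitudes reported for each area in the recordings
# the pipeline targets (e.g. a ~33% collicular and ~30% geniculate response
# reduction, near-total LP/PBG dependence on collicular drive, and a mild
# residual gain change reaching cortex). Suppression parameters are set so
# that the cohort-mean surround suppression index is strong in sSC,
# moderate in V1 (~0.39) and weak in dLGN/LP (~0.2-0.25).
tg_area_params <- function() {
  list(
    sSC  = list(peak = 20, spont = 5.0, gain = 0.67, wc = 10, wsf = 3,
                ks = 3.0, osi = 0.10, dsi = 0.10),
    dLGN = list(peak = 16, spont = 7.9, gain = 0.70, wc = 12, wsf = 3,
                ks = 1.1, osi = 0.08, dsi = 0.08),
    LP   = list(peak = 10, spont = 3.0, gain = 0.34, wc = 30, wsf = 3,
                ks = 0.9, osi = 0.06, dsi = 0.06),
    PBG  = list(peak = 10, spont = 3.0, gain = 0.39, wc = 25, wsf = 3,
                ks = 1.2, osi = 0.06, dsi = 0.06),
    V1   = list(peak = 30, spont = 3.8, gain = 0.70, wc = 10, wsf = 5,
                pool_w = 2.5, sigma = 1.2, osi = 0.20, dsi = 0.09)
  )
}

#' Generate a ground-truth unit cohort
#'
#' Samples one row of true model parameters per unit, per area, from
#' area-specific distributions. The returned table is the `ground truth`
#' against which parameter-recovery tests compare pipeline estimates.
#'
#' Receptive-field centres are drawn within the central +/-30 degrees
#' (azimuth) and +/-20 degrees (elevation) of the screen; peak driven rates
#' are log-normal (substantial between-unit heterogeneity, as in
#' extracellular cohorts); the optogenetic gain is area-specific with
#' modest unit-to-unit jitter and equals 1 for no effect. `pref_size_deg`
#' is the continuous argmax of the unit's noiseless size-tuning curve and
#' `ssi_true` the suppression index of the noiseless curve evaluated on
#' the configured size grid.
#'
#' @param config A [sim_config()].
#' @return A data.frame with one row per unit: identifiers (`unit_id`,
#'   `area`, `depth_rank`), receptive field (`rf_az_deg`, `rf_el_deg`),
#'   rate-model parameters (`peak_rate_hz`, `spont_hz`, `size_wc_deg`,
#'   `size_ws_deg`, `suppression_strength`, `norm_sigma`,
#'   `contrast_c50`, `pref_dir_deg`, `osi_true`, `dsi_true`,
#'   `laser_gain`), and derived truths (`pref_size_deg`, `ssi_true`).
#' @export
#' @examples
#' units <- make_units(sim_config(seed = 1, n_units = c(V1 = 3)))
#' units[, c("unit_id", "area", "pref_size_deg", "ssi_true")]
make_units <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  par <- tg_area_params()
  out <- list()
  uid <- 0L
  for (area in names(config$n_units)) {
    n <- config$n_units[[area]]
    if (n == 0L) next
    p <- par[[area]]
    peak <- rlnorm(n, meanlog = log(p$peak) - 0.5^2 / 2, sdlog = 0.5)
    spont <- rgamma(n, shape = 4, rate = 4 / p$spont)
    wc <- rlnorm(n, meanlog = log(p$wc) - 0.25^2 / 2, sdlog = 0.25)
    ws <- p$wsf * wc
    gain <- pmin(1, pmax(0.05, rnorm(n, p$gain, 0.06)))
    c50 <- rlnorm(n, meanlog = log(30) - 0.2^2 / 2, sdlog = 0.2)
    osi <- rbeta(n, 2, 2 / p$osi - 2)
    dsi <- rbeta(n, 2, 2 / p$dsi - 2)
    # keep the direction profile non-negative (see tg_dir_profile)
    sc <- pmax(1, 2.2 * (osi + dsi))
    osi <- osi / sc
    dsi <- dsi / sc
    if (area == "V1") {
      supp <- rlnorm(n, meanlog = log(p$pool_w) - 0.3^2 / 2, sdlog = 0.3)
      sigma <- rlnorm(n, meanlog = log(p$sigma) - 0.3^2 / 2, sdlog = 0.3)
    } else {
      supp <- rgamma(n, shape = 3, rate = 3 / p$ks)
      sigma <- rep(NA_real_, n)
    }
    df <- data.frame(
      unit_id = sprintf("%s_%03d", area, seq_len(n)),
      area = area,
      depth_rank = seq_len(n),
      rf_az_deg = runif(n, -30, 30),
      rf_el_deg = runif(n, -20, 20),
      peak_rate_hz = peak,
      spont_hz = spont,
      size_wc_deg = wc,
      size_ws_deg = ws,
      suppression_strength = supp,
      norm_sigma = sigma,
      contrast_c50 = c50,
      pref_dir_deg = runif(n, 0, 360),
      osi_true = osi,
      dsi_true = dsi,
      laser_gain = gain,
      stringsAsFactors = FALSE)
    uid <- uid + n
    out[[area]] <- df
  }
  units <- do.call(rbind, out)
  rownames(units) <- NULL
  units$pref_size_deg <- vapply(seq_len(nrow(units)), function(i)
    tg_pref_size_cont(units[i, ]), numeric(1))
  units$ssi_true <- vapply(seq_len(nrow(units)), function(i) {
    r <- model_size_tuning(units[i, ], config$sizes_deg)
    ssi(max(r), r[length(r)])
  }, numeric(1))
  units
}

# Continuous preferred size: argmax of the noiseless size profile over
# (0, 180] degrees.
tg_pref_size_cont <- function(unit) {
  f <- function(s) tg_size_response(unit, s)
  optimize(f, interval = c(1, 180), maximum = TRUE, tol = 1e-4)$maximum
}
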