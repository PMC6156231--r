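# Independent oracles used across test files.

# 1 - circular variance via complex resultant: an implementation of the
# selectivity indices that shares no code with the package's sin/cos sums.
oracle_one_minus_cv <- function(directions_deg, responses, fold) {
  r <- pmax(responses, 0)
  z <- sum(r * exp(1i * fold * directions_deg * pi / 180))
  Mod(z) / sum(r)
}

# A minimal hand-built ground-truth unit row for model tests, bypassing
# make_units so every parameter is explicit.
fixture_unit <- function(area = "dLGN", peak = 20, spont = 4, wc = 12,
                         ws = 36, supp = 1, sigma = NA, c50 = 30,
                         pref_dir = 0, osi = 0.1, dsi = 0.1, gain = 0.7) {
  u <- list(unit_id = paste0(area, "_t"), area = area, depth_rank = 1L,
            rf_az_deg = 0, rf_el_deg = 0, peak_rate_hz = peak,
            spont_hz = spont, size_wc_deg = wc, size_ws_deg = ws,
            suppression_strength = supp, norm_sigma = sigma,
            contrast_c50 = c50, pref_dir_deg = pref_dir, osi_true = osi,
            dsi_true = dsi, laser_gain = gain)
  # continuous preferred size, found independently by grid search
  s_grid <- seq(1, 180, by = 0.05)
  r <- vapply(s_grid, function(s) {
    lc <- (2 * pnorm(sqrt(2) * s / wc) - 1)^2
    ls <- (2 * pnorm(sqrt(2) * s / ws) - 1)^2
    if (area == "V1") lc / (sigma + lc + supp * ls) else lc / (1 + supp * ls)
  }, numeric(1))
  u$pref_size_deg <- s_grid[which.max(r)]
  u
}

# Trial-level data.frame for hand-built tuning tables.
fixture_trials <- function(evoked, size, direction = 0, contrast = 95,
                           laser = FALSE, unit = "u1") {
  data.frame(unit_id = unit, size_deg = size, direction_deg = direction,
             contrast_pct = contrast, laser_on = laser, evoked_hz = evoked,
             stringsAsFactors = FALSE)
}
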