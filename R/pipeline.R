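# End-to-end analysis: spikes + epochs -> tuning tables, indices,
# population curves, statistics, report files.

#' Run the full analysis pipeline on a session
#'
#' Extracts per-trial evoked responses, builds tuning tables, applies the
#' 2 Hz inclusion criterion, computes per-unit SSI/OSI/DSI for both laser
#' states, aligns size tuning on each unit's (laser-off) optimum,
#' aggregates population curves, and runs the statistical battery: paired
#' comparison of optimal-size responses, paired comparison of SSI
#' (excluding units not surround-suppressed at baseline), per-size-step
#' paired comparisons, and a two-way laser x size-step ANOVA interaction
#' test.
#'
#' For the interaction test each unit's curve is normalised, within each
#' laser state, by that state's response at the unit's laser-off preferred
#' size. A pure multiplicative gain change then leaves no interaction (the
#' normalised curves coincide), so the test asks specifically whether the
#' manipulation changed the *shape* of size tuning rather than its gain.
#'
#' If the session contains a contrast series (more than one contrast
#' level), population contrast-response curves at the fixed contrast-series
#' size are computed for both laser states and the contrast-matching
#' procedure is applied.
#'
#' @param session A `"tg_session"` (from [simulate_session()] or
#'   [read_session()]).
#' @param options Named list: `min_response_hz` (inclusion threshold,
#'   default 2), `exclude_zero_ssi` (default `TRUE`), `contrast_target_pct`
#'   and `contrast_tol_pct` for [contrast_match()].
#' @return A list of class `"tg_report"`: `inclusion` (per-unit verdicts),
#'   `indices` (per-unit SSI/OSI/DSI, off and on), `ssi_change`,
#'   `population` (aligned size-tuning means per laser state),
#'   `comparisons` (list of `"comparison_result"`), `interaction`,
#'   `contrast` (match result or `NULL`), `n_included`, and `notice`
#'   (non-`NULL` when the cohort is empty).
#' @export
run_pipeline <- function(session, options = list()) {
  opt <- utils::modifyList(
    list(min_response_hz = 2, exclude_zero_ssi = TRUE,
         contrast_target_pct = 15, contrast_tol_pct = 5),
    options)
  trials <- trial_responses(session$spikes, session$epochs)
  tab <- build_tuning_table(trials)
  ids <- unique(tab$unit_id)
  inc <- vapply(ids, function(id)
    include_unit(tab, id, opt$min_response_hz), logical(1))
  inclusion <- data.frame(unit_id = ids, included = inc,
                          stringsAsFactors = FALSE)
  kept <- ids[inc]
  if (length(kept) == 0L) {
    return(structure(list(inclusion = inclusion, indices = NULL,
                          ssi_change = NULL, population = NULL,
                          comparisons = list(), interaction = NULL,
                          contrast = NULL, n_included = 0L,
                          notice = "empty cohort: no unit passed inclusion"),
                     class = "tg_report"))
  }
  cmax <- max(tab$contrast_pct)
  # per-unit direction-averaged curves, both laser states
  curves <- do.call(rbind, lapply(kept, function(id) {
    off <- size_tuning(tab, id, laser_on = FALSE, contrast_pct = cmax)
    on <- size_tuning(tab, id, laser_on = TRUE, contrast_pct = cmax)
    data.frame(unit_id = id, size_deg = off$size_deg,
               R_off = off$R_hz, R_on = on$R_hz[match(off$size_deg,
                                                      on$size_deg)],
               stringsAsFactors = FALSE)
  }))
  ssi_change <- ssi_change_analysis(curves,
                                    exclude_zero = opt$exclude_zero_ssi)
  # direction indices at the laser-off preferred size
  indices <- do.call(rbind, lapply(kept, function(id) {
    cu <- curves[curves$unit_id == id, ]
    pref <- preferred_size(cu$size_deg, cu$R_off)
    row <- function(laser) {
      sub <- tab[tab$unit_id == id & tab$laser_on == laser &
                   tab$size_deg == pref & tab$contrast_pct == cmax, ]
      if (sum(pmax(sub$mean_hz, 0)) <= 0) return(c(NA_real_, NA_real_))
      c(osi(sub$direction_deg, sub$mean_hz),
        dsi(sub$direction_deg, sub$mean_hz))
    }
    off <- row(FALSE); on <- row(TRUE)
    data.frame(unit_id = id, pref_size_deg = pref,
               r_pref_off = cu$R_off[match(pref, cu$size_deg)],
               r_pref_on = cu$R_on[match(pref, cu$size_deg)],
               r_large_off = cu$R_off[nrow(cu)],
               r_large_on = cu$R_on[nrow(cu)],
               osi_off = off[1], dsi_off = off[2],
               osi_on = on[1], dsi_on = on[2],
               stringsAsFactors = FALSE)
  }))
  indices <- merge(indices, ssi_change[, c("unit_id", "ssi_off", "ssi_on")],
                   by = "unit_id", all.x = TRUE)
  # optimum-aligned population curves
  aligned <- list(off = list(), on = list())
  for (id in kept) {
    cu <- curves[curves$unit_id == id, ]
    pref <- preferred_size(cu$size_deg, cu$R_off)
    aligned$off[[id]] <- align_to_optimal(cu$size_deg, cu$R_off, pref)
    aligned$on[[id]] <- align_to_optimal(cu$size_deg, cu$R_on, pref)
  }
  population <- rbind(
    cbind(laser_on = FALSE, population_align(aligned$off)),
    cbind(laser_on = TRUE, population_align(aligned$on)))
  # statistics
  comparisons <- list()
  ok <- stats::complete.cases(indices[, c("r_pref_off", "r_pref_on")])
  if (sum(ok) >= 3L)
    comparisons$optimal_response <- run_comparison(
      list(off = indices$r_pref_off[ok], on = indices$r_pref_on[ok]),
      paired = TRUE, label = "optimal-size response, laser off vs on")
  sc <- ssi_change[stats::complete.cases(ssi_change), ]
  if (nrow(sc) >= 3L)
    comparisons$ssi <- run_comparison(
      list(off = sc$ssi_off, on = sc$ssi_on), paired = TRUE,
      label = "SSI, laser off vs on (suppressed units)")
  interaction <- tryCatch(shape_interaction_test(curves),
                          error = function(e) NULL)
  # contrast series, if present
  contrast <- NULL
  ctr <- sort(unique(tab$contrast_pct))
  if (length(ctr) > 1L) {
    csize <- unique(tab$size_deg[tab$contrast_pct != cmax])
    if (length(csize) == 1L) {
      crf <- function(laser) vapply(ctr, function(cc) {
        sub <- tab[tab$laser_on == laser & tab$size_deg == csize &
                     tab$contrast_pct == cc & tab$unit_id %in% kept, ]
        mean(tapply(sub$mean_hz, sub$unit_id, mean))
      }, numeric(1))
      r_off <- crf(FALSE); r_on <- crf(TRUE)
      contrast <- tryCatch(
        c(contrast_match(ctr, r_off, r_on,
                         target_pct = opt$contrast_target_pct,
                         tol_pct = opt$contrast_tol_pct),
          list(contrasts_pct = ctr, r_off = r_off, r_on = r_on)),
        tg_no_contrast_match = function(e)
          list(error = conditionMessage(e), contrasts_pct = ctr,
               r_off = r_off, r_on = r_on))
    }
  }
  structure(list(inclusion = inclusion, indices = indices,
                 ssi_change = ssi_change, population = population,
                 comparisons = comparisons, interaction = interaction,
                 contrast = contrast,
                 n_included = length(kept), notice = NULL),
            class = "tg_report")
}

#' @export
print.tg_report <- function(x, ...) {
  cat("<tg_report>\n")
  if (!is.null(x$notice)) {
    cat("  NOTICE:", x$notice, "\n")
    return(invisible(x))
  }
  cat("  included units:", x$n_included, "of", nrow(x$inclusion), "\n")
  sc <- x$ssi_change[stats::complete.cases(x$ssi_change), ]
  if (nrow(sc))
    cat(sprintf("  mean SSI off %.3f -> on %.3f (n = %d suppressed units)\n",
                mean(sc$ssi_off), mean(sc$ssi_on), nrow(sc)))
  for (cm in x$comparisons) print(cm)
  if (!is.null(x$interaction))
    cat(sprintf("  laser x size interaction: p = %.3g\n",
                x$interaction$p_interaction))
  if (!is.null(x$contrast) && is.null(x$contrast$error))
    cat(sprintf("  contrast match: high %g%%, lower %g%% (reduction %.1f%%)\n",
                x$contrast$high_contrast_pct, x$contrast$lower_contrast_pct,
                x$contrast$reduction_pct))
  invisible(x)
}

#' Write a pipeline report to CSV files
#'
#' Emits `inclusion.csv`, `indices.csv`, `ssi_change.csv`,
#' `population_size_tuning.csv`, `comparisons.csv` and `run_log.txt`
#' (seed, package version, options, empty-cohort notice if applicable).
#' Identical inputs produce byte-identical files.
#'
#' @param report A `"tg_report"`.
#' @param dir Output directory.
#' @param seed Seed recorded in the log.
#' @param options Options recorded in the log.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, seed = NA, options = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$inclusion, file.path(dir, "inclusion.csv"),
            row.names = FALSE)
  if (!is.null(report$indices))
    write.csv(report$indices, file.path(dir, "indices.csv"),
              row.names = FALSE)
  if (!is.null(report$ssi_change))
    write.csv(report$ssi_change, file.path(dir, "ssi_change.csv"),
              row.names = FALSE)
  if (!is.null(report$population))
    write.csv(report$population, file.path(dir, "population_size_tuning.csv"),
              row.names = FALSE)
  if (length(report$comparisons)) {
    cmp <- do.call(rbind, lapply(report$comparisons, function(cm)
      data.frame(label = cm$label, test = cm$test, statistic = cm$statistic,
                 p_value = cm$p_value, n = paste(cm$n, collapse = "/"),
                 direction = cm$direction)))
    if (!is.null(report$interaction))
      cmp <- rbind(cmp, data.frame(
        label = "laser x size-step interaction", test = "two-way ANOVA",
        statistic = report$interaction$F_interaction,
        p_value = report$interaction$p_interaction, n = "",
        direction = NA))
    write.csv(cmp, file.path(dir, "comparisons.csv"), row.names = FALSE)
  }
  log <- c(paste("tectogain", as.character(packageVersion("tectogain"))),
           paste("seed:", seed),
           paste("included units:", report$n_included),
           if (!is.null(report$notice)) paste("NOTICE:", report$notice),
           if (length(options))
             paste(names(options), unlist(options), sep = " = "))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
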