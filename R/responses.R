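# Evoked-response extraction.
#
# The evoked response of a trial is the mean rate over the stimulus window
# minus the spontaneous rate, where the spontaneous rate is the mean rate
# in the last 0.5 s before stimulus onset. Responses may be negative at the
# trial level; flooring happens only inside index computations whose
# codomain requires it.

TG_SPONT_WINDOW_S <- 0.5

#' Per-trial evoked responses for one unit
#'
#' @param spike_times_s Sorted spike times of one unit (seconds).
#' @param epochs Epoch table with `onset_s` and `duration_s` (plus any
#'   condition columns, which are carried through).
#' @return `epochs` with added columns `evoked_hz` and `spont_hz`. Epochs
#'   starting less than 0.5 s into the recording are dropped with a
#'   warning.
#' @export
#' @examples
#' ep <- data.frame(onset_s = 1, duration_s = 1)
#' trial_response(c(0.6, 0.9, seq(1.05, 1.95, by = 0.1)), ep)$evoked_hz
trial_response <- function(spike_times_s, epochs) {
  stopifnot(is.numeric(spike_times_s), !is.unsorted(spike_times_s))
  early <- epochs$onset_s < TG_SPONT_WINDOW_S
  if (any(early)) {
    warning(sum(early), " epoch(s) start < 0.5 s into the recording; dropped")
    epochs <- epochs[!early, , drop = FALSE]
  }
  cnt <- function(a, b)
    findInterval(b, spike_times_s) - findInterval(a, spike_times_s)
  n_stim <- cnt(epochs$onset_s, epochs$onset_s + epochs$duration_s)
  n_spont <- cnt(epochs$onset_s - TG_SPONT_WINDOW_S, epochs$onset_s)
  epochs$spont_hz <- n_spont / TG_SPONT_WINDOW_S
  epochs$evoked_hz <- n_stim / epochs$duration_s - epochs$spont_hz
  epochs
}

#' Per-trial evoked responses for a whole session
#'
#' Applies [trial_response()] to every unit of a session's spike table.
#'
#' @param spikes Spike table (`unit_id`, `spike_time_s`, optionally `area`,
#'   `depth_rank`).
#' @param epochs Epoch table.
#' @return Data.frame of trials: one row per unit x epoch.
#' @export
trial_responses <- function(spikes, epochs) {
  ids <- unique(spikes$unit_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    st <- spikes$spike_time_s[spikes$unit_id == ids[i]]
    tr <- trial_response(sort(st), epochs)
    tr$unit_id <- ids[i]
    if ("area" %in% names(spikes))
      tr$area <- spikes$area[match(ids[i], spikes$unit_id)]
    out[[i]] <- tr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate trials into a per-condition tuning table
#'
#' Means, SEMs and trial counts per (unit, size, direction, contrast,
#' laser) cell. Trial order is irrelevant. Cells present in some units but
#' absent in others are flagged via the `"missing_cells"` attribute but the
#' table is still returned.
#'
#' @param trials Output of [trial_responses()] (needs `unit_id`,
#'   `size_deg`, `direction_deg`, `contrast_pct`, `laser_on`,
#'   `evoked_hz`).
#' @return A data.frame of class `"tuning_table"` with columns `unit_id`,
#'   `size_deg`, `direction_deg`, `contrast_pct`, `laser_on`, `mean_hz`,
#'   `sem_hz`, `n_trials`.
#' @export
build_tuning_table <- function(trials) {
  need <- c("unit_id", "size_deg", "direction_deg", "contrast_pct",
            "laser_on", "evoked_hz")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(trials) == 0L) stop("no trials")
  key <- c("unit_id", "size_deg", "direction_deg", "contrast_pct", "laser_on")
  agg <- aggregate(trials["evoked_hz"], trials[key], function(x)
    c(mean = mean(x), sd = sd(x), n = length(x)))
  tab <- data.frame(agg[key],
                    mean_hz = agg$evoked_hz[, "mean"],
                    sem_hz = agg$evoked_hz[, "sd"] /
                      sqrt(agg$evoked_hz[, "n"]),
                    n_trials = as.integer(agg$evoked_hz[, "n"]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$unit_id, tab$contrast_pct, tab$size_deg,
                   tab$direction_deg, tab$laser_on), ]
  rownames(tab) <- NULL
  # flag condition cells that not all units share
  cells <- unique(tab[, c("size_deg", "direction_deg", "contrast_pct",
                          "laser_on")])
  n_units <- length(unique(tab$unit_id))
  cnt <- aggregate(list(k = tab$unit_id),
                   tab[, c("size_deg", "direction_deg", "contrast_pct",
                           "laser_on")], length)
  missing_cells <- cnt[cnt$k < n_units, , drop = FALSE]
  attr(tab, "missing_cells") <- missing_cells
  class(tab) <- c("tuning_table", "data.frame")
  tab
}

#' Direction-averaged size-tuning curve from a tuning table
#'
#' Means over directions of the per-direction cell means, per size, for one
#' unit, one laser state and one contrast ("averaged over all directions").
#'
#' @param table A `"tuning_table"`.
#' @param unit_id Unit to extract.
#' @param laser_on Logical laser state.
#' @param contrast_pct Contrast; defaults to the maximum present.
#' @return Data.frame with `size_deg` and `R_hz`, ordered by size.
#' @export
size_tuning <- function(table, unit_id, laser_on = FALSE,
                        contrast_pct = NULL) {
  sub <- table[table$unit_id == unit_id & table$laser_on == laser_on, ,
               drop = FALSE]
  if (is.null(contrast_pct)) contrast_pct <- max(sub$contrast_pct)
  sub <- sub[sub$contrast_pct == contrast_pct, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no cells for unit ", unit_id, " at that laser/contrast state")
  r <- tapply(sub$mean_hz, sub$size_deg, mean)
  data.frame(size_deg = as.numeric(names(r)), R_hz = as.numeric(r))
}

#' Unit inclusion by minimum evoked response
#'
#' A unit is analysed only if its maximum direction-averaged evoked
#' response, in the laser-off condition, reaches `min_response_hz`
#' (inclusive). The laser-off condition is used so that inclusion is not
#' biased by the manipulation under study.
#'
#' @param table A `"tuning_table"` (may contain several units).
#' @param unit_id Unit to evaluate.
#' @param min_response_hz Threshold in Hz (default 2).
#' @return `TRUE` or `FALSE`.
#' @export
include_unit <- function(table, unit_id, min_response_hz = 2) {
  st <- size_tuning(table, unit_id, laser_on = FALSE)
  max(st$R_hz) >= min_response_hz
}
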