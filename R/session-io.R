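# Session serialization: a JSON manifest pointing at plain-CSV epoch and
# spike tables (plus optional ground truth), so sessions round-trip through
# text files only.

#' Write a session to disk
#'
#' Writes `epochs.csv`, `spikes.csv`, optionally `ground_truth.csv`, and a
#' `manifest.json` naming them together with the analysis options and the
#' generator seed.
#'
#' @param session A `"tg_session"` (or compatible list with `epochs` and
#'   `spikes`).
#' @param dir Output directory (created if needed).
#' @param options Named list of analysis options stored in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir, options = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(session$epochs, file.path(dir, "epochs.csv"), row.names = FALSE)
  write.csv(session$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  manifest <- list(
    format = "tectogain-session",
    version = as.character(packageVersion("tectogain")),
    epochs = "epochs.csv",
    spikes = "spikes.csv",
    seed = if (!is.null(session$config)) session$config$seed else NULL,
    options = options)
  if (!is.null(session$units)) {
    write.csv(session$units, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
    manifest$ground_truth <- "ground_truth.csv"
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a session from a manifest
#'
#' Validates the manifest schema, checks the referenced files exist and
#' have the required columns, sorts spike times within unit (a shuffled
#' spike CSV reads back to the identical canonical session), and checks
#' epoch sanity (positive durations, no overlap).
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A list of class `"tg_session"` with `epochs`, `spikes`,
#'   optionally `units`, and `options`.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(man$format) || man$format != "tectogain-session")
    stop("not a tectogain session manifest: ", manifest_path)
  base <- dirname(manifest_path)
  need_file <- function(rel, what) {
    if (is.null(rel)) stop("manifest lacks a '", what, "' entry")
    p <- file.path(base, rel)
    if (!file.exists(p)) stop(what, " file missing: ", p)
    p
  }
  epochs <- read.csv(need_file(man$epochs, "epochs"))
  spikes <- read.csv(need_file(man$spikes, "spikes"))
  for (cn in c("onset_s", "duration_s", "laser_on"))
    if (!cn %in% names(epochs))
      stop("epochs.csv lacks required column '", cn, "'")
  for (cn in c("unit_id", "spike_time_s"))
    if (!cn %in% names(spikes))
      stop("spikes.csv lacks required column '", cn, "'")
  if (any(epochs$duration_s <= 0))
    stop("epochs.csv: non-positive duration at row(s) ",
         paste(utils::head(which(epochs$duration_s <= 0), 5), collapse = ", "))
  epochs <- epochs[order(epochs$onset_s), , drop = FALSE]
  if (any(diff(epochs$onset_s) < epochs$duration_s[-nrow(epochs)] - 1e-9))
    stop("epochs.csv: overlapping epochs")
  spikes <- spikes[order(spikes$unit_id, spikes$spike_time_s), , drop = FALSE]
  rownames(epochs) <- rownames(spikes) <- NULL
  units <- NULL
  if (!is.null(man$ground_truth)) {
    units <- read.csv(need_file(man$ground_truth, "ground_truth"))
    dangling <- setdiff(unique(spikes$unit_id), units$unit_id)
    if (length(dangling))
      stop("spikes.csv references unit ids absent from ground truth: ",
           paste(utils::head(dangling, 5), collapse = ", "))
  }
  structure(list(epochs = epochs, spikes = spikes, units = units,
                 options = man$options, seed = man$seed),
            class = "tg_session")
}
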