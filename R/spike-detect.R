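#' Threshold spike detection on a filtered voltage trace
#'
#' Detects spikes as threshold crossings at `k_sd` times the standard
#' deviation of the trace, the standard multi-unit extraction for
#' band-passed (500 Hz - 10 kHz) laminar-probe signals. By extracellular
#' convention the default looks for negative-going crossings below
#' `-k_sd * SD`; set `polarity` to `"positive"` or `"absolute"` for the
#' other conventions. Crossings within `refractory_s` of an accepted event
#' are collapsed onto the first.
#'
#' No sorting or clustering is attempted: each trace yields one multi-unit
#' spike train.
#'
#' @param trace Numeric sample vector, or a `"tg_trace"` from
#'   [simulate_voltage()] (in which case `sampling_rate_hz` is taken from
#'   it).
#' @param sampling_rate_hz Samples per second; must be at least 20 kHz.
#' @param k_sd Threshold in standard deviations (default 3).
#' @param refractory_s Collapse window in seconds (default 1 ms).
#' @param polarity `"negative"` (default), `"positive"`, or `"absolute"`.
#' @param robust If `TRUE`, use the median absolute deviation (scaled to
#'   be consistent with the SD for Gaussian noise) instead of the plain
#'   standard deviation.
#' @return Sorted numeric vector of spike times in seconds (time of the
#'   first sample beyond threshold). A constant trace (zero SD) yields no
#'   spikes.
#' @export
#' @examples
#' tr <- simulate_voltage(c(0.1, 0.3), 0.5, seed = 1)
#' detect_spikes(tr)
detect_spikes <- function(trace, sampling_rate_hz = NULL, k_sd = 3,
                          refractory_s = 0.001,
                          polarity = c("negative", "positive", "absolute"),
                          robust = FALSE) {
  if (inherits(trace, "tg_trace")) {
    sampling_rate_hz <- trace$sampling_rate_hz
    trace <- trace$samples
  }
  polarity <- match.arg(polarity)
  if (is.null(sampling_rate_hz))
    stop("sampling_rate_hz required for a bare sample vector")
  if (sampling_rate_hz < 20000)
    stop("sampling_rate_hz must be >= 20000")
  if (length(trace) == 0L) stop("empty trace")
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  s0 <- if (robust) mad(trace) else sd(trace)
  if (!is.finite(s0) || s0 == 0) return(numeric(0))
  thr <- k_sd * s0
  over <- switch(polarity,
                 negative = trace < -thr,
                 positive = trace > thr,
                 absolute = abs(trace) > thr)
  # onsets: first sample of each excursion beyond threshold
  onset <- which(over & !c(FALSE, over[-length(over)]))
  if (length(onset) == 0L) return(numeric(0))
  times <- (onset - 1L) / sampling_rate_hz
  keep <- rep(TRUE, length(times))
  last <- times[1L]
  for (i in seq_along(times)[-1L]) {
    if (times[i] - last < refractory_s) keep[i] <- FALSE else last <- times[i]
  }
  times[keep]
}
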