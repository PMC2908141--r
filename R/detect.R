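#' Estimate the spike-detection threshold from a preprocessed trace
#'
#' The noise scale delta is the plain sample standard deviation of the full
#' preprocessed trace, and the detection threshold is `multiplier * delta`
#' applied symmetrically (±). A median-based robust alternative
#' (`robust = TRUE`, delta = median(|x|)/0.6745) is available for traces
#' with heavy spike contamination.
#'
#' @param trace preprocessed voltage trace (microvolts), length >= 1000.
#' @param multiplier threshold multiple of delta (default 4.5).
#' @param robust use the median-based noise estimate instead of the SD.
#' @return An object of class `vh_threshold` with fields `delta`,
#'   `multiplier`, `threshold`, `polarity = "both"`.
#' @examples
#' thr <- estimate_threshold(rnorm(2000, sd = 2))
#' thr$threshold / thr$delta  # 4.5
#' @export
estimate_threshold <- function(trace, multiplier = 4.5, robust = FALSE) {
  if (length(trace) < 1000)
    stop("trace too short: need >= 1000 samples to estimate the noise scale")
  delta <- if (robust) stats::median(abs(trace)) / 0.6745 else sd(trace)
  if (!is.finite(delta) || delta <= 0)
    stop("degenerate signal: zero-variance trace")
  structure(list(delta = delta, multiplier = multiplier,
                 threshold = multiplier * delta, polarity = "both"),
            class = "vh_threshold")
}

#' Detect threshold-crossing spikes on one electrode
#'
#' One event is emitted per excursion of `|x|` beyond the threshold,
#' timestamped at the extremum sample of the excursion; positive and
#' negative crossings are pooled into one event stream. Events closer than
#' the dead time are merged keeping the larger extremum. A peak-aligned
#' snippet of `window` samples (extremum at sample `window %/% 2 + 1`) is
#' extracted per event; events too close to the segment edge for a full
#' snippet are dropped from both the event table and the waveform matrix.
#'
#' With `interp = TRUE` (the default) each snippet is re-aligned to the
#' sub-sample extremum located by cubic-spline interpolation around the
#' peak, as is standard practice before wavelet spike sorting: without it,
#' the +/-1-sample alignment jitter splits one unit's waveforms into
#' discrete shift families that clustering mistakes for separate units.
#'
#' @param trace preprocessed voltage trace (microvolts).
#' @param fs sampling rate in Hz.
#' @param threshold a `vh_threshold`, or a bare positive number in
#'   microvolts.
#' @param dead_time_ms minimum separation between events in ms.
#' @param window snippet length in samples.
#' @param interp re-align snippets to the spline-interpolated sub-sample
#'   peak.
#' @return List with `events` — a data.frame with columns `t_s` (seconds
#'   from segment start, 0-based sample convention), `amp_uv`, `polarity` —
#'   and `waves`, the n_events x window waveform matrix.
#' @export
detect_spikes <- function(trace, fs, threshold, dead_time_ms = 1, window = 64,
                          interp = TRUE) {
  if (window > length(trace))
    stop("invalid window: snippet window exceeds trace length")
  thr <- if (inherits(threshold, "vh_threshold")) threshold$threshold
         else as.numeric(threshold)
  if (!is.finite(thr) || thr <= 0) stop("invalid threshold")

  empty <- list(
    events = data.frame(t_s = numeric(0), amp_uv = numeric(0),
                        polarity = integer(0)),
    waves = matrix(numeric(0), nrow = 0, ncol = window)
  )
  idx <- which(abs(trace) > thr)
  if (length(idx) == 0) return(empty)

  # split supra-threshold samples into contiguous excursions, take extremum
  run <- cumsum(c(1L, diff(idx) > 1L))
  amp <- abs(trace[idx])
  o <- order(run, -amp)
  peak <- idx[o][!duplicated(run[o])]
  peak <- sort(peak)

  # merge events closer than the dead time, keeping the larger extremum
  dead <- round(dead_time_ms / 1000 * fs)
  if (length(peak) > 1 && dead > 0) {
    keep <- logical(length(peak))
    cur <- 1L
    for (j in 2:length(peak)) {
      if (peak[j] - peak[cur] < dead) {
        if (abs(trace[peak[j]]) > abs(trace[peak[cur]])) cur <- j
      } else {
        keep[cur] <- TRUE
        cur <- j
      }
    }
    keep[cur] <- TRUE
    peak <- peak[keep]
  }

  # full-snippet requirement at the segment edges (2 extra samples for
  # sub-sample interpolation)
  center <- window %/% 2L + 1L
  guard <- if (interp) 3L else 0L
  ok <- peak >= center + guard &
        peak <= length(trace) - (window - center) - guard
  peak <- peak[ok]
  if (length(peak) == 0) return(empty)

  offs <- seq_len(window) - center
  if (interp) {
    waves <- matrix(0, nrow = length(peak), ncol = window)
    for (j in seq_along(peak)) {
      p <- peak[j]
      xs <- (p - (center + 2L)):(p + (window - center + 2L))
      sp <- stats::splinefun(xs, trace[xs])
      # locate the fractional extremum within +/-1 sample of the peak
      fine <- seq(p - 1, p + 1, by = 0.05)
      pf <- fine[which.max(abs(sp(fine)))]
      waves[j, ] <- sp(pf + offs)
    }
  } else {
    waves <- matrix(trace[rep(peak, times = window) +
                          rep(offs, each = length(peak))],
                    nrow = length(peak), ncol = window)
  }
  list(
    events = data.frame(t_s = (peak - 1) / fs, amp_uv = trace[peak],
                        polarity = as.integer(sign(trace[peak]))),
    waves = waves
  )
}

#' Active-electrode criterion
#'
#' An electrode is active when it records at least `min_spikes` spikes in a
#' `window_s`-second segment — 50 spikes per 50 s, i.e. at least 1 Hz.
#'
#' @param min_spikes spike-count threshold.
#' @param window_s segment length in seconds.
#' @return An object of class `vh_activity_criterion`.
#' @export
activity_criterion <- function(min_spikes = 50, window_s = 50) {
  structure(list(min_spikes = min_spikes, window_s = window_s),
            class = "vh_activity_criterion")
}

#' Classify an electrode as active from its segment spike count
#'
#' @param count spike count over one full segment (>= 0).
#' @param criterion a `vh_activity_criterion`.
#' @return Logical: `TRUE` iff `count >= min_spikes`.
#' @examples
#' classify_active(50)  # TRUE
#' classify_active(49)  # FALSE
#' @export
classify_active <- function(count, criterion = activity_criterion()) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("invalid input: spike count must be a non-negative number")
  count >= criterion$min_spikes
}

#' Windowed spike-frequency observations
#'
#' Spike frequency is determined for each 25-s window of recording: a 50-s
#' segment contributes two observations per electrode, `count / 25` Hz in
#' `[0, 25)` and `[25, 50)`.
#'
#' @param times_s event times in seconds from segment start.
#' @param duration_s segment duration (a multiple of `window_s`).
#' @param window_s observation window in seconds.
#' @return Numeric vector of `duration_s / window_s` frequencies in Hz.
#' @export
frequency_series <- function(times_s, duration_s = 50, window_s = 25) {
  n_win <- duration_s / window_s
  if (abs(n_win - round(n_win)) > 1e-9)
    stop("duration must be a whole number of windows")
  n_win <- as.integer(round(n_win))
  if (length(times_s) == 0) return(rep(0, n_win))
  if (any(times_s < 0 | times_s > duration_s))
    stop("inconsistent table: event outside segment bounds")
  w <- pmin(floor(times_s / window_s) + 1L, n_win)  # t == duration -> last window
  counts <- tabulate(w, nbins = n_win)
  counts / window_s
}

#' Run detection across every electrode of a segment
#'
#' Estimates delta per electrode on its own preprocessed trace, extracts
#' threshold-crossing spikes and waveforms, classifies active electrodes
#' and computes 25-s frequency observations.
#'
#' @param segment a preprocessed `vh_segment`.
#' @param multiplier threshold multiple of delta.
#' @param dead_time_ms event dead time in ms.
#' @param window snippet window in samples.
#' @param criterion a `vh_activity_criterion`; for segments shorter than the
#'   criterion window the count is scaled pro rata.
#' @param freq_window_s frequency-observation window in seconds.
#' @return An object of class `vh_detection`: list with `events` (data.frame
#'   with `electrode`, `t_s`, `amp_uv`, `polarity`), `waves` (per-electrode
#'   list of waveform matrices), `counts`, `active` (logical per electrode),
#'   `freq` (electrodes x windows matrix, Hz), `thresholds`.
#' @export
detect_segment <- function(segment, multiplier = 4.5, dead_time_ms = 1,
                           window = 64, criterion = activity_criterion(),
                           freq_window_s = 25) {
  V <- segment$samples
  n_el <- ncol(V)
  fs <- segment$fs
  dur <- segment$duration_s
  min_count <- criterion$min_spikes * dur / criterion$window_s
  freq_window_s <- min(freq_window_s, dur)   # short segments: one window

  waves <- vector("list", n_el)
  counts <- integer(n_el)
  thresholds <- numeric(n_el)
  freq <- matrix(0, nrow = n_el, ncol = as.integer(round(dur / freq_window_s)))
  ev_list <- vector("list", n_el)
  for (e in seq_len(n_el)) {
    thr <- estimate_threshold(V[, e], multiplier)
    det <- detect_spikes(V[, e], fs, thr, dead_time_ms, window)
    counts[e] <- nrow(det$events)
    waves[[e]] <- det$waves
    thresholds[e] <- thr$threshold
    freq[e, ] <- frequency_series(det$events$t_s, dur, freq_window_s)
    if (counts[e] > 0)
      ev_list[[e]] <- cbind(electrode = e, det$events)
  }
  events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(electrode = integer(0), t_s = numeric(0),
                         amp_uv = numeric(0), polarity = integer(0))
  structure(
    list(events = events, waves = waves, counts = counts,
         active = counts >= min_count, freq = freq, thresholds = thresholds,
         duration_s = dur, fs = fs),
    class = "vh_detection"
  )
}
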