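#' Band-pass filter specification
#'
#' Recordings are filtered with a low-pass cutoff of 2.5 kHz and a high-pass
#' cutoff of 85 Hz before spike extraction. The filter family and order are
#' not prescribed by the recording protocol; a 4th-order Butterworth applied
#' forward-backward (zero-phase) is used, the standard choice for spike-band
#' extraction because it preserves spike timing.
#'
#' @param high_pass_cutoff_hz high-pass cutoff in Hz.
#' @param low_pass_cutoff_hz low-pass cutoff in Hz.
#' @param order Butterworth order of each (high-pass and low-pass) section.
#' @param zero_phase apply forward-backward (no group delay) if `TRUE`.
#' @return An object of class `vh_filter_spec`.
#' @export
filter_spec <- function(high_pass_cutoff_hz = 85, low_pass_cutoff_hz = 2500,
                        order = 4, zero_phase = TRUE) {
  if (!(high_pass_cutoff_hz > 0 && high_pass_cutoff_hz < low_pass_cutoff_hz))
    stop("invalid filter: need 0 < high_pass < low_pass")
  structure(list(high_pass_cutoff_hz = high_pass_cutoff_hz,
                 low_pass_cutoff_hz = low_pass_cutoff_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "vh_filter_spec")
}

#' Band-pass filter a single voltage trace
#'
#' Cascades a high-pass and a low-pass Butterworth section (designed with
#' `signal::butter`). In zero-phase mode each section is applied
#' forward-backward with odd-reflection padding of the segment ends, so the
#' passband group delay is zero and onset transients are not detected as
#' spikes.
#'
#' @param x numeric voltage trace (microvolts).
#' @param fs sampling rate in Hz.
#' @param spec a `vh_filter_spec`.
#' @return Filtered trace, same length and units.
#' @export
bandpass_trace <- function(x, fs, spec = filter_spec()) {
  if (spec$low_pass_cutoff_hz >= fs / 2)
    stop("invalid filter: low-pass cutoff at or above Nyquist")
  hp <- signal::butter(spec$order, spec$high_pass_cutoff_hz / (fs / 2),
                       type = "high")
  lp <- signal::butter(spec$order, spec$low_pass_cutoff_hz / (fs / 2),
                       type = "low")
  # pad several high-pass time constants so edge transients die out
  pad <- min(length(x) - 1L, ceiling(6 * fs / spec$high_pass_cutoff_hz))
  if (spec$zero_phase) {
    y <- filtfilt_cpp(x, hp$b, hp$a, pad)
    y <- filtfilt_cpp(y, lp$b, lp$a, pad)
  } else {
    y <- as.numeric(signal::filter(hp, x))
    y <- as.numeric(signal::filter(lp, y))
  }
  y
}

#' Band-pass filter every electrode of a recording segment
#'
#' @param segment a `vh_segment`.
#' @param spec a `vh_filter_spec`.
#' @return The segment with filtered `samples`.
#' @export
bandpass_filter <- function(segment, spec = filter_spec()) {
  V <- segment$samples
  for (e in seq_len(ncol(V))) V[, e] <- bandpass_trace(V[, e], segment$fs, spec)
  segment$samples <- V
  segment
}

#' Remove a least-squares linear trend from a trace
#'
#' Fits `a + b*t` by ordinary least squares over the whole segment and
#' subtracts it, removing spurious slow trends; the output has zero mean and
#' zero best-fit slope.
#'
#' @param x numeric trace of length >= 2.
#' @return Detrended trace.
#' @export
detrend_trace <- function(x) {
  n <- length(x)
  if (n < 2) stop("invalid input: need at least 2 samples to detrend")
  t <- seq_len(n) - (n + 1) / 2          # centred time axis
  b <- sum(t * x) / sum(t * t)
  x - mean(x) - b * t
}

#' Preprocess a recording segment (filter, then detrend)
#'
#' Band-pass filters every electrode and then removes each electrode's
#' least-squares linear trend — the order the two steps are described in the
#' recording protocol. Set `detrend_first = TRUE` to swap them.
#'
#' @param segment a `vh_segment`.
#' @param spec a `vh_filter_spec`.
#' @param detrend apply linear detrending.
#' @param detrend_first detrend before filtering instead of after.
#' @return The preprocessed segment.
#' @export
preprocess_segment <- function(segment, spec = filter_spec(), detrend = TRUE,
                               detrend_first = FALSE) {
  if (detrend && detrend_first) {
    V <- segment$samples
    for (e in seq_len(ncol(V))) V[, e] <- detrend_trace(V[, e])
    segment$samples <- V
  }
  segment <- bandpass_filter(segment, spec)
  if (detrend && !detrend_first) {
    V <- segment$samples
    for (e in seq_len(ncol(V))) V[, e] <- detrend_trace(V[, e])
    segment$samples <- V
  }
  segment
}
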