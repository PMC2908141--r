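#' Construct a biphasic extracellular spike template
#'
#' Templates are a main Gaussian lobe followed by a smaller opposite-polarity
#' rebound lobe — the classic biphasic shape of extracellular action
#' potentials. The extremum sits at the snippet centre (the same sample the
#' detector aligns on), the stated `peak_amplitude_uv` is the absolute
#' extremum, and both ends of the window decay to within 1% of zero so the
#' template can be superposed on a trace without baseline steps.
#'
#' @param peak_amplitude_uv absolute peak amplitude in microvolts (> 0).
#' @param width_ms full width at half maximum of the main lobe, in ms.
#' @param polarity `"negative"` (main lobe downward, the usual extracellular
#'   case) or `"positive"`.
#' @param window snippet length in samples (must match the detector window).
#' @param fs sampling rate in Hz.
#' @param rebound_frac rebound lobe amplitude as a fraction of the peak.
#' @return An object of class `vh_template` with fields `waveform` (length
#'   `window`, microvolts), `peak_amplitude`, `width_ms`, `polarity`, `fs`.
#' @examples
#' tpl <- make_template(100, 0.5, "negative")
#' min(tpl$waveform)  # -100
#' @export
make_template <- function(peak_amplitude_uv, width_ms,
                          polarity = c("negative", "positive"),
                          window = 64, fs = 20000, rebound_frac = 0.33) {
  polarity <- match.arg(polarity)
  if (!is.finite(peak_amplitude_uv) || peak_amplitude_uv <= 0)
    stop("invalid template: peak_amplitude_uv must be > 0")
  if (!is.finite(width_ms) || width_ms <= 0)
    stop("invalid template: width_ms must be > 0")
  width_samp <- width_ms * fs / 1000
  if (width_samp > window / 2)
    stop("invalid template: width too large for window")

  peak_idx <- window %/% 2 + 1L           # detector-aligned centre sample
  i <- seq_len(window)
  sigma <- width_samp / (2 * sqrt(2 * log(2)))   # FWHM -> Gaussian sd
  main <- exp(-((i - peak_idx)^2) / (2 * sigma^2))
  reb_idx <- peak_idx + round(0.8 * width_samp)
  reb_sigma <- 1.2 * sigma
  reb <- rebound_frac * exp(-((i - reb_idx)^2) / (2 * reb_sigma^2))
  w <- main - reb
  # cosine taper over the outer eighth of the window pins both ends to zero
  # without touching the centred extremum
  ramp <- max(2L, window %/% 8L)
  taper <- rep(1, window)
  taper[seq_len(ramp)] <- sin(pi / 2 * (seq_len(ramp) - 1) / ramp)^2
  taper[window + 1L - seq_len(ramp)] <- taper[seq_len(ramp)]
  w <- w * taper
  w <- w / max(abs(w)) * peak_amplitude_uv
  if (polarity == "negative") w <- -w

  if (max(abs(w[c(1L, window)])) > 0.01 * peak_amplitude_uv)
    stop("invalid template: width too large for window (baseline not reached)")

  structure(
    list(waveform = w, peak_amplitude = peak_amplitude_uv,
         width_ms = width_ms, polarity = polarity, fs = fs,
         peak_index = peak_idx),
    class = "vh_template"
  )
}

#' Default library of distinguishable unit templates
#'
#' Up to seven templates with distinct amplitude, width, rebound fraction and
#' polarity, used by the simulator to plant multiple units on one electrode.
#' Peak amplitudes span 8-15x the background noise SD, so every planted spike
#' clears the 4.5-SD detection threshold with a wide margin, while the shape
#' differences put the classes well apart in wavelet-feature space.
#'
#' @param n_units number of templates (1..7).
#' @param noise_sd_uv background noise SD in microvolts; amplitudes scale
#'   with it.
#' @param window,fs snippet length in samples and sampling rate in Hz.
#' @return List of `vh_template`.
#' @export
template_library <- function(n_units, noise_sd_uv = 5, window = 64, fs = 20000) {
  if (n_units < 1 || n_units > 7)
    stop("template library defines 1..7 units")
  amp_mult <- c(8.0, 15.0, 11.5, 9.0, 14.0, 12.5, 10.0)
  width    <- c(0.45, 0.55, 0.30, 0.60, 0.62, 0.72, 0.70)
  rebound  <- c(0.33, 0.28, 0.42, 0.30, 0.36, 0.45, 0.22)
  pol      <- c("negative", "positive", "negative", "positive",
                "negative", "positive", "negative")
  lapply(seq_len(n_units), function(u) {
    make_template(amp_mult[u] * noise_sd_uv, width[u], pol[u],
                  window = window, fs = fs, rebound_frac = rebound[u])
  })
}
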