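#' Background noise and drift model
#'
#' Stationary Gaussian noise plus a slow additive drift: a sub-high-pass
#' sinusoid (default 0.5 Hz, random phase per electrode) and a linear ramp
#' with random slope per electrode. Both drift components lie far below the
#' 85 Hz high-pass cutoff, so preprocessing is expected to remove them.
#'
#' @param sd_uv stationary Gaussian noise SD in microvolts (> 0).
#' @param drift_amplitude_uv sinusoidal drift amplitude in microvolts.
#' @param drift_frequency_hz drift frequency in Hz (must be below 85 Hz).
#' @param ramp_uv maximum linear-ramp excursion over a segment, microvolts.
#' @return An object of class `vh_noise`.
#' @export
noise_model <- function(sd_uv = 5, drift_amplitude_uv = 100,
                        drift_frequency_hz = 0.5, ramp_uv = 50) {
  if (!is.finite(sd_uv) || sd_uv < 0) stop("noise sd must be >= 0")
  if (drift_frequency_hz >= 85)
    stop("drift frequency must lie below the 85 Hz high-pass cutoff")
  structure(list(sd_uv = sd_uv, drift_amplitude_uv = drift_amplitude_uv,
                 drift_frequency_hz = drift_frequency_hz, ramp_uv = ramp_uv),
            class = "vh_noise")
}

#' Render a synthetic MED64-style recording with planted ground truth
#'
#' Chooses `n_active_electrodes` sites from the tissue mask, plants
#' `units_per_active_electrode` units with distinct templates on each (their
#' effective rates sum to the preset's aggregate rate), plants one
#' sub-criterion background unit on the remaining tissue electrodes, and adds
#' Gaussian noise and slow drift everywhere. The returned ground truth
#' records every planted spike and is the answer key for downstream
#' parameter-recovery tests.
#'
#' Planted counts are re-drawn (same RNG stream) in the astronomically rare
#' event that an active electrode receives fewer than 50 spikes or an
#' inactive one 50 or more, so the activity criterion is realized by
#' construction.
#'
#' @param geometry a `vh_geometry`.
#' @param preset a `vh_preset` (see [build_preset()]).
#' @param noise a `vh_noise`.
#' @param duration_s segment duration in seconds (recordings are made in
#'   50-s increments).
#' @param fs sampling rate in Hz (20 kHz).
#' @param seed integer seed; rendering is bit-reproducible given the seed.
#' @param templates list of `vh_template` for the planted units; defaults to
#'   [template_library()] sized to the preset.
#' @param jitter_sd per-spike multiplicative amplitude jitter SD (fraction).
#' @param refractory_ms per-unit refractory period in ms.
#' @param slice_id,segment_id identifiers carried into the segment.
#' @return List with elements `segment` (class `vh_segment`: `samples` is an
#'   n_samples x n_electrodes matrix in microvolts) and `truth` (class
#'   `vh_truth`: per-electrode planted units, spike times and activity flag).
#' @export
render_recording <- function(geometry = array_geometry(),
                             preset = build_preset("control", "basal"),
                             noise = noise_model(),
                             duration_s = 50, fs = 20000, seed = NULL,
                             templates = NULL, jitter_sd = 0.05,
                             refractory_ms = 2,
                             slice_id = 1L, segment_id = 1L) {
  mask <- geometry$ventral_horn_mask
  if (preset$n_active_electrodes > length(mask))
    stop("capacity error: preset demands more active sites than the tissue mask holds")
  if (!is.null(seed)) set.seed(seed)

  n_el <- geometry$n_electrodes
  n_samp <- round(fs * duration_s)
  n_units <- preset$units_per_active_electrode
  if (is.null(templates))
    templates <- template_library(max(n_units, 1L), noise_sd_uv = max(noise$sd_uv, 1))
  window <- length(templates[[1]]$waveform)
  peak_idx <- templates[[1]]$peak_index

  active_sites <- sort(sample(mask, preset$n_active_electrodes))
  inactive_sites <- setdiff(mask, active_sites)

  # background + drift
  V <- matrix(rnorm(n_samp * n_el, 0, noise$sd_uv), nrow = n_samp, ncol = n_el)
  if (noise$drift_amplitude_uv > 0 || noise$ramp_uv > 0) {
    tt <- (seq_len(n_samp) - 1) / fs
    for (e in seq_len(n_el)) {
      phase <- runif(1, 0, 2 * pi)
      slope <- runif(1, -1, 1) * noise$ramp_uv / duration_s
      V[, e] <- V[, e] +
        noise$drift_amplitude_uv * sin(2 * pi * noise$drift_frequency_hz * tt + phase) +
        slope * tt
    }
  }

  min_spikes <- 50  # activity criterion, spikes per 50-s segment
  truth_units <- vector("list", n_el)
  active_flag <- logical(n_el)
  scale_crit <- duration_s / 50  # criterion scales with segment length
  for (e in active_sites) {
    rate_per_unit <- preset$aggregate_rate_hz / n_units
    for (try in 1:5) {
      trains <- lapply(seq_len(n_units), function(u)
        simulate_spike_train(rate_per_unit, duration_s, refractory_ms))
      if (sum(lengths(trains)) >= min_spikes * scale_crit) break
    }
    units <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      st <- trains[[u]]
      w <- templates[[u]]$waveform
      amp <- 1 + jitter_sd * rnorm(length(st))
      for (k in seq_along(st)) {
        p <- round(st[k] * fs) + 1L
        lo <- p - (peak_idx - 1L); hi <- lo + window - 1L
        wlo <- 1L; whi <- window
        if (lo < 1L) { wlo <- 2L - lo; lo <- 1L }
        if (hi > n_samp) { whi <- window - (hi - n_samp); hi <- n_samp }
        if (lo <= hi) V[lo:hi, e] <- V[lo:hi, e] + w[wlo:whi] * amp[k]
      }
      units[[u]] <- list(unit_id = u, template_id = u, rate_hz = rate_per_unit,
                         spike_times = st)
    }
    truth_units[[e]] <- units
    active_flag[e] <- TRUE
  }
  for (e in inactive_sites) {
    for (try in 1:5) {
      st <- simulate_spike_train(preset$inactive_rate_hz, duration_s, refractory_ms)
      if (length(st) < min_spikes * scale_crit) break
    }
    w <- templates[[1]]$waveform
    amp <- 1 + jitter_sd * rnorm(length(st))
    for (k in seq_along(st)) {
      p <- round(st[k] * fs) + 1L
      lo <- p - (peak_idx - 1L); hi <- lo + window - 1L
      wlo <- 1L; whi <- window
      if (lo < 1L) { wlo <- 2L - lo; lo <- 1L }
      if (hi > n_samp) { whi <- window - (hi - n_samp); hi <- n_samp }
      if (lo <= hi) V[lo:hi, e] <- V[lo:hi, e] + w[wlo:whi] * amp[k]
    }
    truth_units[[e]] <- list(list(unit_id = 1L, template_id = 1L,
                                  rate_hz = preset$inactive_rate_hz,
                                  spike_times = st))
  }

  segment <- structure(
    list(samples = V, fs = fs, duration_s = duration_s, geometry = geometry,
         condition = list(genotype = preset$genotype, drug = preset$drug),
         slice_id = slice_id, segment_id = segment_id),
    class = "vh_segment"
  )
  truth <- structure(
    list(units = truth_units, active = active_flag,
         active_sites = active_sites, templates = templates,
         preset = preset),
    class = "vh_truth"
  )
  list(segment = segment, truth = truth)
}

#' @export
print.vh_segment <- function(x, ...) {
  cat(sprintf("<vh_segment> %s/%s slice %s seg %s: %d electrodes x %.0f s @ %g kHz\n",
              x$condition$genotype, x$condition$drug, x$slice_id, x$segment_id,
              ncol(x$samples), x$duration_s, x$fs / 1000))
  invisible(x)
}

#' Total planted spike count in a ground-truth object
#'
#' @param truth a `vh_truth`.
#' @param electrodes optional subset of electrode indices.
#' @return Integer total of planted spikes.
#' @export
truth_spike_count <- function(truth, electrodes = NULL) {
  units <- truth$units
  if (!is.null(electrodes)) units <- units[electrodes]
  sum(vapply(units, function(ul) {
    if (is.null(ul)) return(0L)
    sum(vapply(ul, function(u) length(u$spike_times), integer(1)))
  }, integer(1)))
}
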