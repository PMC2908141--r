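# Shared fixture builders: single-electrode traces with planted units, built
# in code at test time.

# One electrode's raw trace with n_units planted template units whose
# effective rates sum to agg_rate_hz, over Gaussian noise of sd noise_sd.
# Returns the raw trace plus the planted spike times and unit identities.
planted_trace <- function(seed, n_units = 5, agg_rate_hz = 6.08,
                          duration_s = 50, fs = 20000, noise_sd = 5,
                          jitter_sd = 0.05) {
  set.seed(seed)
  tpls <- template_library(max(n_units, 1), noise_sd_uv = noise_sd)
  n <- round(fs * duration_s)
  x <- rnorm(n, 0, noise_sd)
  times <- numeric(0)
  units <- integer(0)
  for (u in seq_len(n_units)) {
    st <- simulate_spike_train(agg_rate_hz / n_units, duration_s, 2)
    w <- tpls[[u]]$waveform
    pk <- tpls[[u]]$peak_index
    for (t_sp in st) {
      p <- round(t_sp * fs) + 1L
      lo <- p - (pk - 1L); hi <- lo + length(w) - 1L
      if (lo >= 1 && hi <= n)
        x[lo:hi] <- x[lo:hi] + w * (1 + jitter_sd * rnorm(1))
    }
    times <- c(times, st)
    units <- c(units, rep(u, length(st)))
  }
  o <- order(times)
  list(trace = x, times = times[o], units = units[o], fs = fs,
       duration_s = duration_s, templates = tpls)
}

# Fraction of planted spikes with a detected event within tol_s, and count
# of detected events matching no planted spike.
match_events <- function(detected_t, planted_t, tol_s = 5e-4) {
  if (length(planted_t) == 0)
    return(list(recall = NA_real_, n_false = length(detected_t)))
  hit <- vapply(planted_t, function(t) any(abs(detected_t - t) <= tol_s),
                logical(1))
  matched <- vapply(detected_t, function(t) any(abs(planted_t - t) <= tol_s),
                    logical(1))
  list(recall = mean(hit), n_false = sum(!matched))
}

# Synthetic waveform set with k well-separated planted classes: class peak
# amplitudes differ by at least sep_mult x the within-class jitter SD.
planted_waveset <- function(seed, k = 3, n_per = 60, window = 64,
                            jitter_sd_uv = 2, sep_mult = 4) {
  set.seed(seed)
  base <- template_library(max(k, 1), noise_sd_uv = 5, window = window)
  W <- NULL
  labels <- integer(0)
  for (cl in seq_len(k)) {
    w <- base[[cl]]$waveform
    block <- matrix(rep(w, n_per), nrow = n_per, byrow = TRUE) +
      matrix(rnorm(n_per * window, 0, jitter_sd_uv), nrow = n_per)
    W <- rbind(W, block)
    labels <- c(labels, rep(cl, n_per))
  }
  stopifnot(min(abs(diff(sort(vapply(base[seq_len(k)], function(t)
    max(abs(t$waveform)), numeric(1)))))) >= sep_mult * jitter_sd_uv)
  list(waves = W, labels = labels)
}
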