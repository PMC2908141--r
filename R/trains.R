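#' Simulate a refractory Poisson spike train
#'
#' Poisson process with dead time: inter-spike intervals are the refractory
#' period plus an exponential gap. The `rate_hz` argument is the *effective*
#' (observed) rate of the process — the underlying exponential intensity is
#' inflated to `rate / (1 - rate * refractory)` so that the expected spike
#' count over the recording equals `rate_hz * duration_s`.
#'
#' @param rate_hz effective firing rate in Hz (>= 0).
#' @param duration_s recording duration in seconds.
#' @param refractory_ms absolute refractory period in ms (> 0).
#' @return Sorted numeric vector of spike times in seconds within
#'   `[0, duration_s]`; every inter-spike interval is at least the
#'   refractory period.
#' @examples
#' st <- simulate_spike_train(6, 50, refractory_ms = 2)
#' min(diff(st)) >= 0.002
#' @export
simulate_spike_train <- function(rate_hz, duration_s, refractory_ms = 2) {
  if (!is.finite(rate_hz) || rate_hz < 0)
    stop("invalid parameter: rate_hz must be >= 0")
  if (duration_s <= 0) stop("invalid parameter: duration_s must be > 0")
  if (refractory_ms <= 0) stop("invalid parameter: refractory_ms must be > 0")
  if (rate_hz == 0) return(numeric(0))
  tau <- refractory_ms / 1000
  rt <- rate_hz * tau
  if (rt >= 1)
    stop("invalid parameter: rate * refractory >= 1, train not realizable")
  lambda <- rate_hz / (1 - rt)

  times <- numeric(0)
  t_last <- 0
  first <- TRUE
  repeat {
    n_draw <- max(32L, ceiling((duration_s - t_last) * rate_hz * 1.5) + 32L)
    gaps <- tau + rexp(n_draw, lambda)
    if (first) {
      gaps[1] <- gaps[1] - tau  # no dead time before the first spike
      first <- FALSE
    }
    new_t <- t_last + cumsum(gaps)
    times <- c(times, new_t)
    t_last <- times[length(times)]
    if (t_last > duration_s) break
  }
  times[times <= duration_s]
}
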