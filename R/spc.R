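#' Superparamagnetic clustering configuration
#'
#' Parameters of the Potts-model clustering used for spike sorting. The
#' defaults follow the published defaults of the wavelet/superparamagnetic
#' sorting method: q = 20 Potts states, 11 nearest neighbours, temperature
#' grid 0-0.20 in steps of 0.01, minimum cluster size 15.
#'
#' @param q number of Potts spin states.
#' @param k_neighbors neighbours in the point-adjacency graph.
#' @param temperatures increasing temperature scan grid.
#' @param sweeps Swendsen-Wang measurement sweeps per temperature.
#' @param burn_in burn-in sweeps discarded before measuring correlations.
#' @param min_cluster_size smallest group reported as a unit (>= 2).
#' @param seed RNG seed; clustering is deterministic given it.
#' @return An object of class `vh_spc_config`.
#' @export
spc_config <- function(q = 20, k_neighbors = 11,
                       temperatures = seq(0, 0.20, by = 0.01),
                       sweeps = 100, burn_in = 20,
                       min_cluster_size = 15, seed = 1) {
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
  structure(list(q = as.integer(q), k_neighbors = as.integer(k_neighbors),
                 temperatures = temperatures, sweeps = as.integer(sweeps),
                 burn_in = as.integer(burn_in),
                 min_cluster_size = as.integer(min_cluster_size),
                 seed = as.integer(seed)),
            class = "vh_spc_config")
}

#' Superparamagnetic clustering of spike features
#'
#' Maps spikes to q-state Potts spins on a symmetrized k-nearest-neighbour
#' graph with distance-decaying ferromagnetic couplings, runs Swendsen-Wang
#' dynamics across the temperature grid, links spike pairs whose spin-spin
#' correlation exceeds 0.5, and takes connected components of the linked
#' graph as clusters at each temperature. The working temperature is chosen
#' by a cluster-count stability rule: the start of the longest temperature
#' plateau over which the count of clusters with at least
#' `min_cluster_size` members stays constant (and positive) — the
#' superparamagnetic phase, where the natural groups persist after splitting
#' apart and before melting. Clusters of at least `min_cluster_size` spikes are
#' labelled 1, 2, ... by decreasing size; remaining spikes are unassigned
#' (label 0).
#'
#' @param features a `vh_features` or a bare numeric feature matrix
#'   (spikes x features).
#' @param cfg a `vh_spc_config`.
#' @return An object of class `vh_units`: list with `labels` (one per
#'   spike; 0 = unassigned), `n_units`, `temperature`, `cluster_sizes`,
#'   `n_clusters_by_temperature`.
#' @export
spc_cluster <- function(features, cfg = spc_config()) {
  X <- if (inherits(features, "vh_features")) features$features else as.matrix(features)
  if (!all(is.finite(X))) stop("features must be finite")
  n <- nrow(X)
  if (n < 2 * cfg$min_cluster_size)
    stop("insufficient data: need at least ", 2 * cfg$min_cluster_size, " spikes")

  # clustering owns its RNG stream; the caller's stream is left untouched
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  lab <- spc_scan_cpp(X, cfg$k_neighbors, cfg$q, cfg$temperatures,
                      cfg$burn_in, cfg$sweeps)
  n_big <- apply(lab, 2, function(l) sum(table(l) >= cfg$min_cluster_size))
  t_idx <- select_temperature(n_big)
  labels_raw <- lab[, t_idx]
  sizes <- sort(table(labels_raw), decreasing = TRUE)
  big <- sizes[sizes >= cfg$min_cluster_size]
  labels <- integer(n)
  for (u in seq_along(big))
    labels[labels_raw == as.integer(names(big)[u])] <- u
  structure(
    list(labels = labels, n_units = length(big),
         temperature = cfg$temperatures[t_idx],
         cluster_sizes = as.integer(big),
         n_clusters_by_temperature = n_big),
    class = "vh_units"
  )
}

# Cluster-count stability rule for the working temperature.
#
# As temperature rises the system passes from the ferromagnetic phase (one
# or few big clusters), through the superparamagnetic phase (the natural
# groups, stable over a wide temperature range), to the paramagnetic phase
# (everything melts into fragments below min_cluster_size). The number of
# clusters of at least min_cluster_size members is therefore constant over
# the superparamagnetic window and changes rapidly outside it. The working
# temperature is the first temperature of the longest run of constant,
# positive cluster count (ties broken toward higher temperature): the
# beginning of the most persistent plateau, right after the last split,
# where cluster cohesion — and hence the fraction of assigned spikes — is
# greatest.
select_temperature <- function(n_big) {
  r <- rle(n_big)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values >= 1L
  if (!any(ok)) return(1L)
  len <- ifelse(ok, r$lengths, -1L)
  best <- max(which(len == max(len)))
  starts[best]
}

#' @export
print.vh_units <- function(x, ...) {
  cat(sprintf("<vh_units> %d units at T = %.2f (sizes: %s; %d unassigned)\n",
              x$n_units, x$temperature,
              paste(x$cluster_sizes, collapse = ", "),
              sum(x$labels == 0)))
  invisible(x)
}

#' Sort one electrode's waveform matrix into units
#'
#' Convenience wrapper: wavelet feature extraction followed by
#' superparamagnetic clustering.
#'
#' @param waves n_spikes x window waveform matrix.
#' @param cfg a `vh_spc_config`.
#' @param n_select wavelet coefficients to keep.
#' @return A `vh_units` object (see [spc_cluster()]).
#' @export
sort_electrode <- function(waves, cfg = spc_config(), n_select = 10) {
  feats <- extract_features(waves, n_select = n_select,
                            min_cluster_size = cfg$min_cluster_size)
  spc_cluster(feats, cfg)
}

#' Mean number of sorted units per active electrode
#'
#' @param n_units integer vector of per-electrode unit counts over the
#'   active electrodes of a slice.
#' @return Arithmetic mean; `NA` when there are no active electrodes (an
#'   undefined mean is reported as missing, not zero).
#' @examples
#' count_units(c(4, 4, 4, 5))  # 4.25
#' @export
count_units <- function(n_units) {
  if (length(n_units) == 0) return(NA_real_)
  mean(n_units)
}
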