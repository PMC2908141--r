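#' Orthonormal Haar discrete wavelet transform
#'
#' Multi-level orthonormal Haar analysis: at each level, pairwise sums and
#' differences scaled by 1/sqrt(2). Coefficients are returned as
#' `c(approximation at the deepest level, details deepest..1)`, length equal
#' to the input. Being orthonormal, the transform preserves the Euclidean
#' norm and is exactly inverted by [haar_idwt()].
#'
#' @param x numeric vector whose length is divisible by `2^levels`.
#' @param levels decomposition depth.
#' @return Numeric coefficient vector of the same length.
#' @export
haar_dwt <- function(x, levels = 4) {
  n <- length(x)
  if (n %% 2^levels != 0)
    stop("length must be divisible by 2^levels")
  details <- list()
  a <- x
  for (l in seq_len(levels)) {
    odd <- a[seq(1, length(a), by = 2)]
    evn <- a[seq(2, length(a), by = 2)]
    details[[l]] <- (odd - evn) / sqrt(2)
    a <- (odd + evn) / sqrt(2)
  }
  c(a, unlist(details[rev(seq_len(levels))], use.names = FALSE))
}

#' Inverse orthonormal Haar transform
#'
#' @param coef coefficient vector as produced by [haar_dwt()].
#' @param levels decomposition depth used in the forward transform.
#' @return Reconstructed signal.
#' @export
haar_idwt <- function(coef, levels = 4) {
  n <- length(coef)
  if (n %% 2^levels != 0)
    stop("length must be divisible by 2^levels")
  na <- n / 2^levels
  a <- coef[seq_len(na)]
  pos <- na
  for (l in rev(seq_len(levels))) {
    nd <- n / 2^l
    d <- coef[pos + seq_len(nd)]
    pos <- pos + nd
    out <- numeric(2 * nd)
    out[seq(1, 2 * nd, by = 2)] <- (a + d) / sqrt(2)
    out[seq(2, 2 * nd, by = 2)] <- (a - d) / sqrt(2)
    a <- out
  }
  a
}

#' Lilliefors-type deviation-from-normality score
#'
#' Kolmogorov-Smirnov distance between the empirical CDF of a sample and the
#' normal CDF with the sample's own mean and SD. Wavelet coefficients that
#' deviate most from normality across spikes are the ones whose values are
#' multimodal — i.e. the ones that discriminate units — so this score ranks
#' coefficients for feature selection.
#'
#' @param x numeric sample, n >= 8.
#' @return The KS distance; 0 for a zero-variance sample (no discriminative
#'   power).
#' @export
normality_deviation <- function(x) {
  n <- length(x)
  if (n < 8) stop("insufficient data: need n >= 8")
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  z <- sort((x - mean(x)) / s)
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Wavelet feature extraction for spike sorting
#'
#' Computes the full multi-level Haar decomposition of each peak-aligned
#' snippet, scores every coefficient by its deviation from normality across
#' spikes, and retains the top-scoring coefficients as the feature matrix.
#'
#' @param waves n_spikes x window waveform matrix (microvolts).
#' @param n_select number of coefficients to keep (default 10).
#' @param levels Haar decomposition depth.
#' @param min_cluster_size minimum cluster size the downstream clustering
#'   uses; at least twice this many spikes are required.
#' @return An object of class `vh_features`: list with `features`
#'   (n_spikes x n_select), `selected_indices`, `scores` (all coefficients),
#'   `family = "haar"`, `levels`.
#' @export
extract_features <- function(waves, n_select = 10, levels = 4,
                             min_cluster_size = 15) {
  if (!is.matrix(waves)) waves <- matrix(waves, nrow = 1)
  n <- nrow(waves)
  if (n < 2 * min_cluster_size)
    stop("insufficient data: need at least ", 2 * min_cluster_size, " spikes")
  C <- t(apply(waves, 1, haar_dwt, levels = levels))
  scores <- apply(C, 2, normality_deviation)
  n_select <- min(n_select, ncol(C))
  sel <- order(scores, decreasing = TRUE)[seq_len(n_select)]
  structure(
    list(features = C[, sel, drop = FALSE], selected_indices = sel,
         scores = scores, family = "haar", levels = levels),
    class = "vh_features"
  )
}
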