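#' Summarize one slice's detection results
#'
#' The three per-slice quantities reported for each condition: the number of
#' active electrodes, the mean of the 25-s spike-frequency observations over
#' active electrodes, and the total spikes per minute summed over active
#' electrodes.
#'
#' @param counts per-electrode spike counts for the segment.
#' @param active logical per-electrode activity flags.
#' @param freq electrodes x windows matrix of 25-s frequency observations
#'   (Hz).
#' @param duration_s segment duration in seconds.
#' @param n_units optional per-electrode sorted unit counts (NA where not
#'   sorted); averaged over active electrodes.
#' @param condition optional list/character condition labels carried into
#'   the row.
#' @return One-row data.frame: `n_active`, `mean_frequency_hz`,
#'   `spikes_per_min`, `mean_units` plus condition columns.
#' @export
summarize_slice <- function(counts, active, freq, duration_s = 50,
                            n_units = NULL, condition = NULL) {
  n_el <- length(counts)
  if (length(active) != n_el || nrow(freq) != n_el)
    stop("inconsistent input: counts, active and freq must cover the same electrodes")
  n_active <- sum(active)
  mean_f <- if (n_active > 0) mean(freq[active, , drop = FALSE]) else NA_real_
  total_spm <- sum(counts[active]) * 60 / duration_s
  mean_u <- if (!is.null(n_units) && n_active > 0)
    mean(n_units[active], na.rm = TRUE) else NA_real_
  out <- data.frame(n_active = n_active, mean_frequency_hz = mean_f,
                    spikes_per_min = total_spm, mean_units = mean_u)
  if (!is.null(condition)) {
    for (nm in names(condition)) out[[nm]] <- condition[[nm]]
  }
  out
}

#' Pooled, per-slice-normalized firing-rate histogram
#'
#' Each slice's frequency observations are weighted by one over that slice's
#' total number of observations — every slice contributes total mass 1
#' regardless of how many active electrodes it has — then pooled across
#' slices and binned at `bin_width` Hz, bins left-closed right-open starting
#' at 0.
#'
#' @param obs_by_slice list of numeric vectors, one per slice, of 25-s
#'   frequency observations (Hz, >= 0).
#' @param bin_width bin width in Hz (default 0.5).
#' @return data.frame with `bin_left`, `bin_right`, `weight`; the weights
#'   sum to the number of slices.
#' @examples
#' h <- build_histogram(list(c(0.2, 0.3, 0.7)))
#' h$weight  # 2/3, 1/3
#' @export
build_histogram <- function(obs_by_slice, bin_width = 0.5) {
  if (!is.list(obs_by_slice)) obs_by_slice <- list(obs_by_slice)
  if (any(vapply(obs_by_slice, length, integer(1)) == 0))
    stop("each slice must contribute at least one observation")
  all_obs <- unlist(obs_by_slice, use.names = FALSE)
  if (any(all_obs < 0)) stop("invalid input: negative frequency observation")
  w <- unlist(lapply(obs_by_slice, function(x) rep(1 / length(x), length(x))),
              use.names = FALSE)
  n_bins <- max(1L, ceiling((max(all_obs) + 1e-12) / bin_width))
  bin <- pmin(floor(all_obs / bin_width) + 1L, n_bins)
  weight <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
  data.frame(bin_left = (seq_len(n_bins) - 1) * bin_width,
             bin_right = seq_len(n_bins) * bin_width,
             weight = weight)
}

#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Standard EM for a K-component univariate Gaussian mixture, run from
#' `n_starts` kmeans++-style seeded initializations and keeping the best
#' final log-likelihood. Convergence is declared when the log-likelihood
#' gain per observation falls below `tol`; component variances are floored
#' to avoid collapse onto single points. Components are returned sorted by
#' mean.
#'
#' @param x numeric observations (n >= 10*K).
#' @param K number of components (3 fits the observed firing-rate
#'   distributions).
#' @param n_starts random restarts.
#' @param seed RNG seed for the restarts.
#' @param max_iter maximum EM iterations per start.
#' @param tol per-observation log-likelihood convergence tolerance.
#' @param var_floor variance lower bound; default `1e-6 * var(x)`.
#' @return An object of class `vh_gmm`: `weights`, `means`, `variances`,
#'   `loglik` (final), `loglik_trace`, `n_iter`, `converged`.
#' @export
fit_gmm <- function(x, K = 3, n_starts = 10, seed = 1, max_iter = 500,
                    tol = 1e-8, var_floor = NULL) {
  n <- length(x)
  if (n < 10 * K)
    stop("insufficient data: need at least ", 10 * K, " observations")
  if (is.null(var_floor)) var_floor <- max(1e-6 * var(x), 1e-12)

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  kmeanspp_centers <- function(x, K) {
    centers <- numeric(K)
    centers[1] <- x[sample.int(length(x), 1)]
    if (K == 1) return(centers)
    for (k in 2:K) {
      d2 <- vapply(x, function(xi) min((xi - centers[1:(k - 1)])^2), numeric(1))
      if (sum(d2) == 0) centers[k] <- x[sample.int(length(x), 1)]
      else centers[k] <- x[sample.int(length(x), 1, prob = d2)]
    }
    centers
  }

  em_once <- function(mu0) {
    pi_k <- rep(1 / K, K)
    mu <- mu0
    s2 <- rep(max(var(x) / K, var_floor), K)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(K), function(k)
        pi_k[k] * dnorm(x, mu[k], sqrt(s2[k])), numeric(n))
      rowsum_d <- rowSums(dens)
      rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
      ll <- sum(log(rowsum_d))
      ll_trace <- c(ll_trace, ll)
      r <- dens / rowsum_d
      nk <- colSums(r)
      pi_k <- nk / n
      mu <- colSums(r * x) / nk
      s2 <- pmax(colSums(r * (outer(x, mu, "-")^2)) / nk, var_floor)
      if (is.finite(ll_old) && (ll - ll_old) < tol * n) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(pi = pi_k, mu = mu, s2 = s2, ll = ll_trace[length(ll_trace)],
         trace = ll_trace, n_iter = length(ll_trace), converged = converged)
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- em_once(kmeanspp_centers(x, K))
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  o <- order(best$mu)
  structure(
    list(K = K, weights = best$pi[o], means = best$mu[o],
         variances = best$s2[o], loglik = best$ll,
         loglik_trace = best$trace, n_iter = best$n_iter,
         converged = best$converged),
    class = "vh_gmm"
  )
}

#' @export
print.vh_gmm <- function(x, ...) {
  cat(sprintf("<vh_gmm> K = %d, logLik = %.3f (%d iter%s)\n", x$K, x$loglik,
              x$n_iter, if (x$converged) ", converged" else ""))
  for (k in seq_len(x$K))
    cat(sprintf("  pi = %.3f  mu = %.3f Hz  sd = %.3f Hz\n",
                x$weights[k], x$means[k], sqrt(x$variances[k])))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H on pooled mid-ranks with a chi-square
#' reference distribution (`stats::kruskal.test`); significance is assessed
#' at alpha = 0.01, the level used for spike-frequency distribution
#' comparisons.
#'
#' @param groups list of 2 or more numeric observation vectors.
#' @param alpha significance level.
#' @return List with `H`, `df`, `p_value`, `significant`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$H  # 7.2
#' @export
kruskal_wallis <- function(groups, alpha = 0.01) {
  if (!is.list(groups) || length(groups) < 2)
    stop("invalid design: need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 1))
    stop("invalid design: each group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("invalid design: need at least 3 observations")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1) {
    # all observations tied: no rank variation, H defined as 0
    return(list(H = 0, df = length(groups) - 1L, p_value = 1,
                significant = FALSE))
  }
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  list(H = H, df = unname(kt$parameter), p_value = kt$p.value,
       significant = kt$p.value < alpha)
}

#' One-way analysis of variance across groups
#'
#' Classical between/within variance decomposition with an F reference
#' distribution (`stats::oneway.test` with equal variances assumed);
#' significance at alpha = 0.05.
#'
#' @param groups list of 2 or more numeric vectors, each of length >= 2.
#' @param alpha significance level.
#' @return List with `F`, `df_between`, `df_within`, `p_value`,
#'   `significant`.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("invalid design: need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("invalid design: each group needs at least two observations")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  grand <- mean(x)
  ss_between <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df_b <- length(groups) - 1L
  df_w <- length(x) - length(groups)
  if (ss_within == 0) {
    # degenerate: no within-group spread; F defined as 0 when between is 0
    Fv <- if (ss_between == 0) 0 else Inf
    p <- if (ss_between == 0) 1 else 0
  } else {
    Fv <- (ss_between / df_b) / (ss_within / df_w)
    p <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  list(F = Fv, df_between = df_b, df_within = df_w, p_value = p,
       significant = p < alpha)
}

#' Compare condition-level summaries
#'
#' Builds the condition table of mean and SEM for the three per-slice
#' quantities, runs a one-way ANOVA on each quantity across conditions, and
#' — when per-slice frequency observations are supplied — a Kruskal-Wallis
#' test on the pooled observations between conditions.
#'
#' @param summaries data.frame of per-slice summary rows (from
#'   [summarize_slice()]) with a `condition` column.
#' @param freq_obs optional named list (by condition) of lists of per-slice
#'   frequency-observation vectors.
#' @return List with `table` (condition, n_slices, mean/SEM columns;
#'   dispersion reported is the SEM), `anova` (per-quantity results),
#'   `kruskal` (or NULL).
#' @export
compare_conditions <- function(summaries, freq_obs = NULL) {
  if (!"condition" %in% names(summaries))
    stop("summaries must carry a 'condition' column")
  conds <- unique(summaries$condition)
  if (length(conds) < 2) stop("need at least two conditions")
  sem <- function(v) sd(v) / sqrt(length(v))
  metrics <- c("n_active", "mean_frequency_hz", "spikes_per_min")
  tab <- do.call(rbind, lapply(conds, function(cc) {
    s <- summaries[summaries$condition == cc, ]
    row <- data.frame(condition = cc, n_slices = nrow(s))
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(s[[m]])
      row[[paste0(m, "_sem")]] <- sem(s[[m]])
    }
    row
  }))
  aov_res <- lapply(metrics, function(m) {
    groups <- lapply(conds, function(cc)
      summaries[[m]][summaries$condition == cc])
    names(groups) <- conds
    if (any(vapply(groups, length, integer(1)) < 2)) return(NULL)
    anova_oneway(groups)
  })
  names(aov_res) <- metrics
  kw <- NULL
  if (!is.null(freq_obs)) {
    pooled <- lapply(freq_obs, function(slices) unlist(slices, use.names = FALSE))
    kw <- kruskal_wallis(pooled)
  }
  list(table = tab, anova = aov_res, kruskal = kw, dispersion = "SEM")
}
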