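test_that("slice summaries follow the counting identities", {
  # 2 active electrodes at exactly 6 Hz for 50 s
  counts <- c(300, 300, 10)
  active <- c(TRUE, TRUE, FALSE)
  freq <- rbind(c(6, 6), c(6, 6), c(0.2, 0.2))
  s <- summarize_slice(counts, active, freq)
  expect_equal(s$n_active, 2)
  expect_equal(s$spikes_per_min, 720)
  expect_equal(s$mean_frequency_hz, 6)

  s0 <- summarize_slice(c(1, 2), c(FALSE, FALSE), rbind(c(0, 0), c(0, 0)))
  expect_equal(s0$n_active, 0)
  expect_true(is.na(s0$mean_frequency_hz))
  expect_equal(s0$spikes_per_min, 0)

  expect_error(summarize_slice(1:3, c(TRUE, FALSE), rbind(0, 0)),
               "inconsistent input")
})

test_that("histograms are per-slice normalized with left-closed 0.5 Hz bins", {
  h <- build_histogram(list(c(0.2, 0.3, 0.7)))
  expect_equal(h$bin_left, c(0, 0.5))
  expect_equal(h$weight, c(2 / 3, 1 / 3))

  # each slice contributes total mass 1 regardless of its size
  h2 <- build_histogram(list(rep(0.2, 10), rep(0.7, 3)))
  expect_equal(h2$weight, c(1, 1))

  set.seed(1)
  slices <- lapply(1:5, function(i) runif(sample(3:40, 1), 0, 12))
  h3 <- build_histogram(slices)
  expect_equal(sum(h3$weight), 5, tolerance = 1e-12)

  # boundary observation falls in the right-open bin above it
  h4 <- build_histogram(list(c(0.5)))
  expect_equal(h4$weight, c(0, 1))

  expect_error(build_histogram(list(c(0.2, -1))), "invalid input")
  expect_error(build_histogram(list(numeric(0))), "at least one")
})

test_that("a single-component EM fit lands on the closed-form optimum", {
  set.seed(2)
  x <- rnorm(500, 3, 2)
  fit <- fit_gmm(x, K = 1, n_starts = 2)
  expect_equal(fit$means, mean(x), tolerance = 1e-6)
  expect_equal(fit$variances, mean((x - mean(x))^2), tolerance = 1e-6)
  expect_equal(fit$weights, 1, tolerance = 1e-9)
})

test_that("EM recovers the generating three-component mixture", {
  set.seed(3)
  n <- 3000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  mu_true <- c(1.5, 5.5, 9.0)
  sd_true <- c(0.6, 0.8, 1.0)
  x <- rnorm(n, mu_true[comp], sd_true[comp])
  fit <- fit_gmm(x, K = 3, seed = 4)
  expect_true(all(abs(fit$means - mu_true) < 0.3))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))   # EM monotonicity
  expect_true(fit$converged)

  # data order does not matter (same optimum from restarts)
  fit2 <- fit_gmm(sample(x), K = 3, seed = 4)
  expect_equal(fit2$means, fit$means, tolerance = 1e-3)

  # richer models never fit worse
  ll <- vapply(1:3, function(k) fit_gmm(x, K = k, seed = 5)$loglik, numeric(1))
  expect_true(all(diff(ll) > 0))

  expect_error(fit_gmm(rnorm(20), K = 3), "insufficient")
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(5)
  x <- c(rnorm(600, 2, 0.5), rnorm(400, 7, 1))
  fit <- fit_gmm(x, K = 2, seed = 6)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(unname(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3 * abs(mc$loglik))
})

test_that("Kruskal-Wallis matches the rank-sum oracle and its invariances", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$H, 7.2)         # 12/(N(N+1)) * sum R_i^2/n_i - 3(N+1)
  expect_equal(r$df, 2L)

  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_lt(same$H, 1e-9)

  ties <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_identical(ties$H, 0)
  expect_identical(ties$p_value, 1)

  # invariant under strictly monotone transforms
  g <- list(rnorm(10), rnorm(12, 1), rnorm(8, 2))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, exp))$H, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(1:3)), "invalid design")
})

test_that("one-way ANOVA matches the pooled-t oracle and affine invariance", {
  r <- anova_oneway(list(c(3, 4, 5), c(6, 7, 8)))
  # two-group F equals the square of the pooled two-sample t statistic
  t_stat <- (7 - 4) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(r$F, t_stat^2)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 4L)

  expect_identical(anova_oneway(list(c(1, 2), c(1, 2), c(1, 2)))$F, 0)

  set.seed(6)
  g <- list(rnorm(10), rnorm(10, 0.5), rnorm(10, 1))
  r1 <- anova_oneway(g)
  r2 <- anova_oneway(lapply(g, function(v) 3 * v - 7))
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)

  expect_error(anova_oneway(list(1:3)), "invalid design")
  expect_error(anova_oneway(list(1, 1:2)), "invalid design")
})

test_that("condition comparison reports SEM and detects a planted rate shift", {
  s <- data.frame(n_active = c(4, 6, 14, 16),
                  mean_frequency_hz = c(5, 6, 10, 11),
                  spikes_per_min = c(1000, 1200, 5000, 5200),
                  condition = c("a", "a", "b", "b"))
  rep_ <- compare_conditions(s)
  expect_equal(rep_$table$n_active_mean, c(5, 15))
  expect_equal(rep_$table$n_active_sem, c(1, 1))  # {4,6}: mean 5, SEM 1
  expect_identical(rep_$dispersion, "SEM")

  # identical conditions: nothing significant
  s2 <- s; s2$condition <- c("a", "a", "a", "a"); s2$condition[3:4] <- "b"
  s2[3:4, 1:3] <- s2[1:2, 1:3]
  rep2 <- compare_conditions(s2)
  expect_false(rep2$anova$n_active$significant)

  # planted basal -> serotonin rate shift is detected by Kruskal-Wallis
  set.seed(7)
  basal <- lapply(1:6, function(i) rpois(30, 6.08 * 25) / 25)
  sero <- lapply(1:6, function(i) rpois(30, 10.20 * 25) / 25)
  s3 <- rbind(s, s)  # table content irrelevant for the rank test
  s3$condition <- rep(c("basal", "serotonin"), each = 4)
  rep3 <- compare_conditions(s3, freq_obs = list(basal = basal,
                                                 serotonin = sero))
  expect_true(rep3$kruskal$significant)
  expect_lt(rep3$kruskal$p_value, 0.01)
})
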