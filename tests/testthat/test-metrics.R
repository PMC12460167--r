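# Metric definitions against independent loop-based oracles and
# hand-evaluated fixtures.

# Naive loop implementations, kept deliberately free of the package's
# vectorized code paths.
oracle_rmse <- function(R, P) {
  s <- 0
  for (m in seq_len(nrow(R))) for (t in seq_len(ncol(R))) s <- s + (R[m, t] - P[m, t])^2
  sqrt(s / (nrow(R) * ncol(R)))
}
oracle_corr_expl <- function(R1, R2, P1, P2) {
  50 * (stats::cor(c(t(R1)), c(t(P1))) + stats::cor(c(t(R2)), c(t(P2)))) /
    stats::cor(c(t(R1)), c(t(R2)))
}
oracle_var_expl <- function(R1, R2, E1, E2) {
  MT <- length(R1)
  pv <- function(x) sum((x - sum(x) / MT)^2) / MT
  s_noise <- 0.5 * pv(R1 - R2)
  num <- sum((R1 - E1)^2) / (2 * MT) + sum((R2 - E2)^2) / (2 * MT) - s_noise
  den <- 0.5 * (pv(R1) + pv(R2)) - s_noise
  100 * (1 - num / den)
}
oracle_loglik_pois <- function(lam, R) {
  s <- 0
  for (m in seq_len(nrow(R))) for (t in seq_len(ncol(R))) {
    s <- s + R[m, t] * log(lam[m, t]) - lam[m, t] - lfactorial(R[m, t])
  }
  s / length(R)
}

test_that("metrics agree with loop-based oracles to 1e-10 on random fixtures", {
  set.seed(11)
  for (rep in 1:5) {
    # correlated trial pairs (shared signal) so the denominators are positive
    sig <- matrix(stats::rpois(100, 1.2), 5, 20)
    R1 <- sig + matrix(stats::rpois(100, 0.4), 5, 20)
    R2 <- sig + matrix(stats::rpois(100, 0.4), 5, 20)
    P1 <- sig + matrix(stats::rpois(100, 0.4), 5, 20)
    P2 <- sig + matrix(stats::rpois(100, 0.4), 5, 20)
    E1 <- sig + matrix(stats::runif(100, 0, 0.8), 5, 20)
    E2 <- sig + matrix(stats::runif(100, 0, 0.8), 5, 20)
    pair <- trial_pair(R1, R2, rhat1 = P1, rhat2 = P2)
    pair_e <- trial_pair(R1, R2, rhat1 = E1, rhat2 = E2)
    expect_equal(rmse_metric(R1, P1), oracle_rmse(R1, P1), tolerance = 1e-10)
    expect_equal(correlation_explained(pair),
                 oracle_corr_expl(R1, R2, P1, P2), tolerance = 1e-10)
    expect_equal(variance_explained(pair_e),
                 oracle_var_expl(as.vector(R1), as.vector(R2),
                                 as.vector(E1), as.vector(E2)),
                 tolerance = 1e-10)
    lam <- matrix(stats::runif(100, 0.2, 2), 5, 20)
    dp <- count_distribution("poisson", lambda = lam)
    expect_equal(loglik_metric(dp, R1), oracle_loglik_pois(lam, R1),
                 tolerance = 1e-10)
  }
})

test_that("perfect predictions on noise-free pairs return exactly 100%", {
  R <- matrix(stats::rpois(100, 1), 5, 20)
  dist <- count_distribution("poisson", lambda = pmax(R, 1e-9))
  pair <- trial_pair(R, R, rhat1 = R, rhat2 = R, dist1 = dist, dist2 = dist)
  expect_equal(correlation_explained(pair), 100)
  expect_equal(variance_explained(pair), 100)
  # grand-mean prediction with zero noise explains exactly 0%
  gm <- matrix(mean(R), nrow(R), ncol(R))
  pair0 <- trial_pair(R, R, rhat1 = gm, rhat2 = gm)
  expect_equal(variance_explained(pair0), 0)
})

test_that("hand-computed metric fixtures are exact", {
  R <- rbind(c(0, 2), c(1, 1)); P <- rbind(c(1, 2), c(1, 3))
  expect_equal(rmse_metric(R, P), sqrt(5 / 4))
  expect_equal(rmse_metric(R, R), 0)
  expect_equal(rmse_metric(R, R + 1), 1)
  expect_error(rmse_metric(matrix(numeric(0), 0, 0), matrix(numeric(0), 0, 0)),
               "empty")
})

test_that("correlation explained handles noise, swaps and degeneracy", {
  set.seed(12)
  M <- 5; Tn <- 20000
  R1 <- matrix(stats::rpois(M * Tn, 1), M); R1[1, 1] <- R1[1, 1] + 1
  R2 <- R1 + matrix(stats::rpois(M * Tn, 0.3), M) - matrix(stats::rpois(M * Tn, 0.3), M)
  # swapped trials as predictions: numerator equals denominator
  pair_swap <- trial_pair(R1, R2, rhat1 = R2, rhat2 = R1)
  expect_equal(correlation_explained(pair_swap), 100, tolerance = 1e-9)
  # uncorrelated noise predictions stay near zero
  pair_noise <- trial_pair(R1, R2,
                           rhat1 = matrix(stats::rpois(M * Tn, 1), M),
                           rhat2 = matrix(stats::rpois(M * Tn, 1), M))
  expect_lt(abs(correlation_explained(pair_noise)), 5)
  # negative trial-pair correlation is flagged undefined
  a <- matrix(rep(c(0, 2), 50), 1); b <- matrix(rep(c(2, 0), 50), 1)
  expect_warning(v <- correlation_explained(trial_pair(a, b, rhat1 = a, rhat2 = b)),
                 "undefined")
  expect_true(is.na(v))
})

test_that("variance explained goes negative for bad predictions", {
  set.seed(13)
  R1 <- matrix(stats::rpois(2000, 1), 4)
  R2 <- matrix(stats::rpois(2000, 1), 4)
  bad <- matrix(5, 4, 500)
  expect_lt(suppressWarnings(variance_explained(trial_pair(R1, R2, rhat1 = bad,
                                                           rhat2 = bad))), 0)
})

test_that("coherence is 1 for identical trials and scale-invariant", {
  set.seed(14)
  R1 <- matrix(stats::rpois(3 * 1600, 1), 3)
  ch <- coherence_metric(trial_pair(R1, R1), n_bins = 763)
  expect_equal(range(ch$coherence), c(1, 1), tolerance = 1e-9)
  # per-unit scaling of both trials cancels
  R2 <- matrix(stats::rpois(3 * 1600, 1), 3)
  base <- coherence_metric(trial_pair(R1, R2), n_bins = 256)
  scl <- coherence_metric(trial_pair(R1 * 3, R2 * 3), n_bins = 256)
  expect_equal(base$coherence, scl$coherence, tolerance = 1e-9)
  # independent noise: mean coherence near 1/n_segments
  set.seed(15)
  A <- matrix(stats::rnorm(8 * 4096), 8); B <- matrix(stats::rnorm(8 * 4096), 8)
  nseg <- 4096 %/% 256
  chn <- coherence_metric(trial_pair(A, B), n_bins = 256)
  expect_lt(abs(mean(chn$coherence[-1]) - 1 / nseg), 0.5 / nseg)
})

test_that("Fano factors follow the population variance-to-mean definition", {
  # identical trials: zero variance
  R <- array(rep(matrix(stats::rpois(40, 1), 2), 3), c(2, 20, 3))
  expect_equal(fano_factor(R)$fano, c(0, 0))
  # counts {0,2,0,2} across 4 trials in one bin: var = mean = 1
  R2 <- array(0, c(1, 1, 4)); R2[1, 1, ] <- c(0, 2, 0, 2)
  expect_equal(fano_factor(R2)$fano, 1)
  # Poisson simulation at 128 trials is near 1
  set.seed(16)
  R3 <- array(stats::rpois(1 * 500 * 128, 1.5), c(1, 500, 128))
  expect_equal(fano_factor(R3)$fano, 1, tolerance = 0.03)
  # zero-mean bins are masked
  R4 <- array(0, c(1, 10, 4)); R4[1, 1, ] <- c(1, 1, 1, 1)
  expect_equal(fano_factor(R4)$n_bins_used, 1)
})

test_that("synchrony equals the analytic value for a cosine rate", {
  rateb <- bin_rate()
  f <- 16 * rateb / 763  # integer number of cycles inside the window
  r <- matrix(1 + cos(2 * pi * f * (0:999) / rateb), 1, 1000)
  s <- synchrony_mtf(r, f, onset_s = 0, window_start = 0, n_bins = 763)
  expect_equal(s$synchrony, 0.25, tolerance = 1e-9)
  # invariant to multiplicative scaling
  s2 <- synchrony_mtf(5 * r, f, onset_s = 0, window_start = 0, n_bins = 763)
  expect_equal(s2$synchrony, s$synchrony, tolerance = 1e-12)
  # constant response: zero at all modulation frequencies
  s0 <- synchrony_mtf(matrix(2, 1, 1000), c(4, 16, 64), onset_s = 0,
                      window_start = 0, n_bins = 763)
  expect_true(all(s0$synchrony < 1e-20))
})

test_that("analysis windows use the single bin-conversion rule", {
  # the 7.9-ms start excludes exactly the first 6 bins
  b <- window_bins(0.0079, 0.05)
  expect_equal(b[1], 7)
  expect_equal(max(b), 38)
  expect_length(window_bins(0, 0.0079), 6)
})

test_that("tuning summaries average the annotated windows", {
  ann <- tibble::tibble(onset_s = c(0, 0.2), duration_s = 0.05, label = "tone",
                        freq_hz = c(1000, 2000), level_db = 60)
  R <- matrix(2, 3, 400)
  resp <- mua_response(R)
  ts <- tuning_summary(resp, ann)
  expect_true(all(ts$mean_count == 2))
  expect_equal(nrow(ts), 6)
  ann_bad <- tibble::tibble(onset_s = 10, duration_s = 0.05, label = "tone",
                            freq_hz = 1000, level_db = 60)
  expect_error(tuning_summary(resp, ann_bad), "beyond the recording")
})

test_that("the non-stationarity index detects drift and ignores unit order", {
  set.seed(17)
  base <- matrix(stats::rpois(6 * 2000, 1.5), 6)
  noisy <- function(g) matrix(stats::rpois(6 * 2000, 1.5 * g), 6) + base
  e1 <- noisy(1); e2 <- noisy(1)
  # stationary: late trials share the early statistics
  l1 <- noisy(1); l2 <- noisy(1)
  idx_stat <- nonstationarity_index(list(e1, e2), list(l1, l2))
  # gain drop late in the session
  l1d <- noisy(0.3); l2d <- noisy(0.3)
  idx_drift <- nonstationarity_index(list(e1, e2), list(l1d, l2d))
  expect_gt(idx_drift, idx_stat)
  perm <- sample(6)
  expect_equal(nonstationarity_index(list(e1[perm, ], e2[perm, ]),
                                     list(l1d[perm, ], l2d[perm, ])),
               idx_drift, tolerance = 1e-12)
  expect_error(nonstationarity_index(list(e1, e2[, 1:10]), list(l1, l2)))
})

test_that("bottleneck PCA normalizes against silence and partitions variance", {
  set.seed(18)
  sil <- matrix(stats::rnorm(8 * 100, 5, 0.01), 8)
  # rank-1 response on top of the silence floor
  u <- stats::rnorm(8); v <- stats::rnorm(300)
  bn <- rowMeans(sil) + u %o% v
  pc <- bottleneck_pca(bn, sil)
  expect_equal(pc$variance_fraction[1], 1, tolerance = 1e-6)
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-9)
  # silence input maps to (near) zero normalized response
  pc0 <- bottleneck_pca(matrix(rowMeans(sil), 8, 200), sil)
  expect_lt(max(abs(pc0$normalized)), 1e-9)
  expect_error(bottleneck_pca(matrix(1, 8, 4), sil), "underdetermined")
})

test_that("bootstrap CIs tighten with the number of units", {
  set.seed(19)
  v_small <- stats::rnorm(20, 50, 10)
  v_large <- stats::rnorm(320, 50, 10)
  b_small <- bootstrap_metric(v_small, n_boot = 400, seed = 1)
  b_large <- bootstrap_metric(v_large, n_boot = 400, seed = 1)
  w_small <- b_small$ci_hi - b_small$ci_lo
  w_large <- b_large$ci_hi - b_large$ci_lo
  expect_lt(w_large, w_small / 2)  # ~1/sqrt(16) ideally
  expect_true(b_small$ci_lo <= b_small$boot_median &&
                b_small$boot_median <= b_small$ci_hi)
})
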