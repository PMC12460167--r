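# The encoder-decoder: activations, likelihoods, shapes, causality,
# gradients, sampling and the mel/LNP baseline.

test_that("the symmetric log activation is odd, monotone and exact", {
  expect_identical(symmetric_log(0), 0)
  expect_equal(symmetric_log(exp(1) - 1), 1)
  x <- seq(-5, 5, by = 0.1)
  expect_equal(symmetric_log(-x), -symmetric_log(x))
  expect_true(all(diff(symmetric_log(x)) > 0))
})

test_that("count losses match hand-evaluated values", {
  expect_equal(poisson_loss(matrix(1), matrix(0)), 1)
  expect_equal(poisson_loss(matrix(2), matrix(3)), 2 - 3 * log(2))
  # per-bin Poisson loss is minimized at lambda = R
  lams <- seq(0.5, 6, by = 0.01)
  losses <- lams - 3 * log(lams)
  expect_equal(lams[which.min(losses)], 3, tolerance = 0.011)
  expect_warning(expect_equal(poisson_loss(matrix(0), matrix(2)), Inf), "zero rate")

  p_right <- array(0, c(1, 1, 5)); p_right[1, 1, 3] <- 1
  expect_equal(categorical_loss(p_right, matrix(2)), 0)
  p_unif <- array(1 / 5, c(2, 3, 5))
  expect_equal(categorical_loss(p_unif, matrix(1, 2, 3)), 6 * log(5))
  expect_warning(expect_equal(categorical_loss(p_right, matrix(4)), Inf),
                 "zero probability")
})

test_that("log-likelihood metric averages the observed-count mass", {
  # p = 0.5 on counts 0 and 1
  d <- count_distribution("categorical", prob = array(c(0.5, 0.5, 0, 0, 0),
                                                      c(1, 1, 5)))
  expect_equal(loglik_metric(d, matrix(1)), log(0.5))
  dp <- count_distribution("poisson", lambda = matrix(1))
  expect_equal(loglik_metric(dp, matrix(0)), -1)
  p_right <- array(0, c(1, 1, 5)); p_right[1, 1, 1] <- 1
  expect_equal(loglik_metric(count_distribution("categorical", prob = p_right),
                             matrix(0)), 0)
})

test_that("the forward pass honours the frame arithmetic and causality", {
  cfg <- small_cfg()
  m <- build_model(cfg, units = 3, seed = 1)
  x <- stats::rnorm(cfg$frame + cfg$context, 0, 0.04)
  fw <- spikecoder:::model_forward(m, x)
  expect_equal(fw$T_out, cfg$frame / 32)
  expect_error(spikecoder:::model_forward(m, x[-1]), "context")
  # categorical rows sum to 1
  sums <- apply(fw$dist$prob, c(1, 3, 4), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
  # causality: perturbing the tail never changes earlier bins
  x2 <- x
  k <- 40  # inspect bins 1..k, perturb strictly after their receptive field
  cut <- cfg$context + k * 32
  x2[(cut + 1):length(x2)] <- x2[(cut + 1):length(x2)] + 0.5
  fw2 <- spikecoder:::model_forward(m, x2)
  expect_equal(fw$dist$prob[seq_len(k), , , 1], fw2$dist$prob[seq_len(k), , , 1],
               tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients on all paths", {
  set.seed(1)
  for (spec in list(list(nc = 5, tm = "bottleneck"),
                    list(nc = 1, tm = "audio"),
                    list(nc = 5, tm = "bottleneck_complex"))) {
    cfg <- micro_cfg(n_classes = spec$nc, time_module = spec$tm)
    m <- build_model(cfg, units = 2, seed = 3)
    B <- 2; Tin <- cfg$frame + cfg$context; Tb <- cfg$frame / 32
    sound <- matrix(stats::rnorm(Tin * B, 0, 0.05), Tin, B)
    tau <- if (spec$tm == "audio") matrix(7200 + seq_len(Tin * B) / 24414, Tin, B)
           else matrix(7200 + stats::runif(Tb * B), Tb, B)
    Rarr <- array(sample(0:4, Tb * 2 * B, TRUE), c(Tb, 2, B))
    lossf <- function(mm) {
      fw <- spikecoder:::model_forward(mm, sound, tau, 1, training = TRUE)
      hl <- spikecoder:::head_loss_grad(fw, Rarr, cfg$n_classes)
      list(fw = fw, loss = hl$loss, dz = hl$dz)
    }
    bl <- lossf(m)
    g <- spikecoder:::model_backward(m, bl$fw, bl$dz)
    flat_g <- unlist(g); flat_p <- unlist(m$params)
    idx <- sample(length(flat_p), 10)
    for (i in idx) {
      eps <- 1e-5
      m1 <- m; m1$params <- utils::relist(replace(flat_p, i, flat_p[i] + eps), m$params)
      m2 <- m; m2$params <- utils::relist(replace(flat_p, i, flat_p[i] - eps), m$params)
      num <- (lossf(m1)$loss - lossf(m2)$loss) / (2 * eps)
      expect_equal(flat_g[[i]], num, tolerance = 1e-3,
                   label = sprintf("%s/%s grad leaf %d", spec$nc, spec$tm, i))
    }
  }
})

test_that("a constant time input makes the model stationary", {
  cfg <- micro_cfg(time_module = "bottleneck")
  m <- build_model(cfg, units = 2, seed = 4)
  x <- stats::rnorm(cfg$frame + cfg$context, 0, 0.04)
  Tb <- cfg$frame / 32
  f1 <- spikecoder:::model_forward(m, x, matrix(3600, Tb, 1))
  f2 <- spikecoder:::model_forward(m, x, matrix(3600, Tb, 1))
  f3 <- spikecoder:::model_forward(m, x, matrix(30000, Tb, 1))
  expect_identical(f1$dist$prob, f2$dist$prob)
  expect_false(identical(f1$dist$prob, f3$dist$prob))
})

test_that("sampling reproduces the predicted distribution", {
  # degenerate categorical: all draws equal the certain count
  p <- array(0, c(2, 5, 5)); p[, , 3] <- 1
  s <- sample_response(count_distribution("categorical", prob = p), seed = 1)
  expect_true(all(s$counts == 2))
  # Poisson with zero rate: all zeros
  s0 <- sample_response(count_distribution("poisson",
                                           lambda = matrix(0, 2, 50)), seed = 1)
  expect_true(all(s0$counts == 0))
  # empirical class frequencies match p within a 3-sigma binomial band
  pr <- c(0.35, 0.3, 0.2, 0.1, 0.05)
  n <- 1e5
  pm <- array(rep(pr, each = n), c(1, n, 5))
  draws <- sample_response(count_distribution("categorical", prob = pm),
                           seed = 7)$counts
  freq <- tabulate(draws + 1, 5) / n
  expect_true(all(abs(freq - pr) <= 3 * sqrt(pr * (1 - pr) / n)))
  # reproducible from seed
  expect_identical(sample_response(count_distribution("categorical", prob = pm),
                                   seed = 7)$counts, draws)
})

test_that("expected counts and sampled dispersion are consistent", {
  p <- array(0, c(1, 1, 5)); p[1, 1, 1] <- 0.5; p[1, 1, 5] <- 0.5
  expect_equal(as.vector(expected_counts(count_distribution("categorical", prob = p))), 2)
  expect_equal(as.vector(expected_counts(count_distribution("poisson",
                                                            lambda = matrix(0.3)))), 0.3)
  # binomial(4, 1/4) head gives Fano near 0.75; Poisson head near 1
  n <- 4000
  pb <- array(rep(stats::dbinom(0:4, 4, 0.25), each = n), c(1, n, 5))
  db <- count_distribution("categorical", prob = pb)
  arr <- array(0, c(1, n, 24))
  for (i in 1:24) arr[, , i] <- sample_response(db, seed = i)$counts
  expect_equal(fano_factor(arr)$fano, 0.75, tolerance = 0.05)
  dp <- count_distribution("poisson", lambda = matrix(0.5, 1, n))
  for (i in 1:24) arr[, , i] <- sample_response(dp, seed = 100 + i)$counts
  expect_equal(fano_factor(arr)$fano, 1, tolerance = 0.07)
})

test_that("mel spectrograms run at the count-bin frame rate", {
  expect_equal(bin_rate(), 24414.0625 / 32)
  x <- stats::rnorm(8192, 0, 0.04)
  S <- mel_spectrogram(x)
  expect_equal(ncol(S), 256)
  expect_equal(nrow(S), 96)
  expect_equal(attr(S, "frame_rate_hz"), 762.9395, tolerance = 1e-4)
  expect_error(mel_spectrogram(stats::rnorm(100)), "shorter than one")
  # silence maps to a constant floor across frames
  S0 <- mel_spectrogram(numeric(4096))
  expect_equal(max(apply(S0, 1, stats::sd)), 0)
})

test_that("the LNP baseline computes rates and recovers kernels", {
  spec <- matrix(stats::runif(12 * 400), 12, 400)
  k0 <- array(0, c(3, 12, 8))
  expect_true(all(lnp_forward(spec, k0)$lambda == 1))  # exp(0)
  # single-tap identity kernel: lambda = exp(spec value)
  k1 <- array(0, c(1, 12, 1)); k1[1, 5, 1] <- 1
  expect_equal(as.vector(lnp_forward(spec, k1)$lambda), exp(spec[5, ]),
               tolerance = 1e-12)
  # parameter recovery from LNP-generated counts
  set.seed(3)
  spec_l <- matrix(stats::runif(12 * 2000), 12, 2000)
  ktrue <- array(stats::rnorm(2 * 12 * 4, 0, 0.4), c(2, 12, 4))
  lam <- lnp_forward(spec_l, ktrue)$lambda
  R <- matrix(stats::rpois(length(lam), lam), nrow(lam))
  fit <- lnp_fit(spec_l, R, n_taps = 4, steps = 600, lr = 0.1, seed = 5)
  cc <- stats::cor(as.vector(fit$kernels), as.vector(ktrue))
  expect_gt(cc, 0.9)
})
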