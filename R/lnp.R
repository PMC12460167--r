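# Linear-nonlinear (LNP) baseline: mel-spectrogram front end and per-unit
# Poisson regression with causal spectro-temporal kernels.

# STFT power at the count-bin frame rate (rate/hop = 762.9395 Hz at the
# canonical settings); the frame count equals length(x) %/% hop. Two
# alignments: "left" (windows start at the frame position, reflect padding
# at the end -- the spectrogram front-end convention) and "causal" (windows
# end at the frame's last sample, zero padding at the start -- used by the
# response simulator so a bin's drive never depends on future audio).
# Scaled so a unit-RMS sinusoid at a bin centre carries unit power.
stft_power <- function(x, window = 512, hop = 32, rate = audio_rate(),
                       align = c("left", "causal")) {
  align <- match.arg(align)
  n <- length(x)
  if (n < window) stop("input shorter than one analysis window", call. = FALSE)
  n_frames <- n %/% hop
  pad <- window - hop
  if (align == "left") {
    xp <- c(x, x[seq(n - 1, by = -1, length.out = min(pad, n - 1))])
    if (length(xp) < (n_frames - 1) * hop + window) {
      xp <- c(xp, numeric((n_frames - 1) * hop + window - length(xp)))
    }
  } else {
    xp <- c(numeric(pad), x)
  }
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(window) - 1) / window))  # Hann
  starts <- (seq_len(n_frames) - 1) * hop
  nk <- window %/% 2 + 1
  P <- matrix(0, nk, n_frames)
  chunk <- 16384L  # frames per block, keeps the working set bounded
  for (i0 in seq(1, n_frames, by = chunk)) {
    ks <- i0:min(i0 + chunk - 1, n_frames)
    fr <- vapply(starts[ks], function(s) xp[s + seq_len(window)] * w,
                 numeric(window))
    X <- stats::mvfft(fr)
    P[, ks] <- 2 * Mod(X[seq_len(nk), , drop = FALSE])^2 / sum(w)^2
  }
  P[1, ] <- P[1, ] / 2  # d.c. is not doubled
  attr(P, "freq_hz") <- (seq_len(nk) - 1) * rate / window
  attr(P, "frame_rate_hz") <- rate / hop
  P
}

# Triangular mel filterbank (bands x fft bins).
mel_filterbank <- function(freq_hz, n_bands, f_lo, f_hi) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(f_lo), mel(f_hi), length.out = n_bands + 2))
  fb <- matrix(0, n_bands, length(freq_hz))
  for (b in seq_len(n_bands)) {
    lo <- edges[b]; mid <- edges[b + 1]; hi <- edges[b + 2]
    up <- (freq_hz - lo) / (mid - lo)
    dn <- (hi - freq_hz) / (hi - mid)
    fb[b, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Mel spectrogram at the count-bin frame rate
#'
#' Short-time power spectra (window 512 samples, hop 32) mapped to
#' logarithmically spaced mel bands, expressed in dB with a positive offset,
#' and squashed through a sigmoid so values live in (0, 1). The hop of 32
#' samples locks the frame rate to the 762.9395 Hz count bins; an input of
#' 8,192 samples yields 256 frames.
#'
#' @param x a `sound_stimulus` or waveform at the canonical rate
#' @param window,hop STFT window and step in samples
#' @param n_bands number of mel bands
#' @param f_lo,f_hi band range in Hz
#' @param offset_db offset added to the dB values
#' @param squash apply the sigmoid normalization?
#' @param rate sampling rate
#' @return bands x frames matrix with attribute `frame_rate_hz`
#' @export
mel_spectrogram <- function(x, window = 512, hop = 32, n_bands = 96,
                            f_lo = 50, f_hi = 12000, offset_db = 7,
                            squash = TRUE, rate = audio_rate()) {
  s <- if (inherits(x, "sound_stimulus")) x$samples else as.numeric(x)
  P <- stft_power(s, window, hop, rate)
  fb <- mel_filterbank(attr(P, "freq_hz"), n_bands, f_lo, f_hi)
  E <- fb %*% P
  L <- 10 * log10(E + 1e-12) + offset_db
  out <- if (squash) sigmoid(L) else L
  attr(out, "frame_rate_hz") <- attr(P, "frame_rate_hz")
  out
}

# im2col over the time axis of a (bands x frames) spectrogram with causal
# left zero padding: returns (bands*taps) x frames.
spec_unfold <- function(S, n_taps) {
  nb <- nrow(S); Tn <- ncol(S)
  Sp <- cbind(matrix(0, nb, n_taps - 1), S)
  out <- matrix(0, nb * n_taps, Tn)
  for (k in seq_len(n_taps)) {
    out[(k - 1) * nb + seq_len(nb), ] <- Sp[, k + seq_len(Tn) - 1, drop = FALSE]
  }
  out
}

#' LNP forward pass
#'
#' Per-unit causal convolution of the mel spectrogram with a
#' spectro-temporal kernel, followed by an exponential nonlinearity, giving
#' a Poisson rate per unit per frame.
#'
#' @param spec bands x frames mel spectrogram
#' @param kernels units x bands x taps kernel array (taps = 64 by default
#'   at full scale); all-zero kernels give rate 1 everywhere
#' @return a Poisson `count_distribution` (units x frames)
#' @export
lnp_forward <- function(spec, kernels) {
  stopifnot(length(dim(kernels)) == 3, dim(kernels)[2] == nrow(spec))
  n_units <- dim(kernels)[1]; n_taps <- dim(kernels)[3]
  if (ncol(spec) < n_taps) stop("spectrogram shorter than the kernel", call. = FALSE)
  Xc <- spec_unfold(spec, n_taps)
  # kernel layout must match the unfold: offset-k blocks, band within block
  Wm <- matrix(0, n_units, nrow(Xc))
  for (k in seq_len(n_taps)) {
    Wm[, (k - 1) * nrow(spec) + seq_len(nrow(spec))] <-
      matrix(kernels[, , k], n_units, nrow(spec))
  }
  lam <- exp(Wm %*% Xc)
  count_distribution("poisson", lambda = lam)
}

#' Fit an LNP model by penalized Poisson regression
#'
#' Adam gradient descent on the Poisson loss with an L2 penalty on the
#' kernels (factor 1e-5 by default).
#'
#' @param spec bands x frames mel spectrogram
#' @param R units x frames observed counts
#' @param n_taps kernel length in frames
#' @param l2 L2 penalty factor
#' @param lr learning rate
#' @param steps gradient steps
#' @param seed initialization seed
#' @return list with `kernels` (units x bands x taps) and the loss trace
#' @export
lnp_fit <- function(spec, R, n_taps = 64, l2 = 1e-5, lr = 0.05, steps = 300,
                    seed = 1L) {
  if (inherits(R, "mua_response")) R <- R$counts
  stopifnot(ncol(spec) == ncol(R))
  nb <- nrow(spec); n_units <- nrow(R); Tn <- ncol(R)
  Xc <- spec_unfold(spec, n_taps)
  W <- with_seed(derive_seed(seed, "lnp"),
                 matrix(stats::rnorm(n_units * nb * n_taps, 0, 1e-3),
                        n_units, nb * n_taps))
  st <- adam_init(list(W = W))
  loss_trace <- numeric(steps)
  for (i in seq_len(steps)) {
    lam <- exp(W %*% Xc)
    loss_trace[i] <- sum(lam - R * (W %*% Xc)) / (n_units * Tn) + l2 * sum(W^2)
    g <- ((lam - R) %*% t(Xc)) / (n_units * Tn) + 2 * l2 * W
    up <- adam_step(list(W = W), list(W = g), st, lr)
    W <- up$params$W; st <- up$state
  }
  kernels <- array(0, c(n_units, nb, n_taps))
  for (k in seq_len(n_taps)) kernels[, , k] <- W[, (k - 1) * nb + seq_len(nb)]
  list(kernels = kernels, loss = loss_trace)
}
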