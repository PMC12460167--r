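# Low-level neural-network operations on (time, channel, batch) arrays:
# causal strided 1D convolution via im2col + BLAS, parametric rectifiers,
# the symmetric-log activation, likelihood heads, and their exact
# backward passes. All state is explicit; caches returned by the forward
# passes feed the corresponding backward passes.

# ---- convolution -----------------------------------------------------------

# Gather-index matrices depend only on the layer geometry; build once and
# reuse across training steps.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_gather_idx <- function(Tn, C, B, K, stride) {
  key <- paste(Tn, C, B, K, stride, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Tp <- Tn + K - 1L
  T_out <- (Tp - K) %/% stride + 1L
  starts <- (seq_len(T_out) - 1L) * stride + 1L
  base <- outer(starts, 0:(K - 1L), "+")                       # (T_out, K)
  flat <- outer(base, (seq_len(C) - 1L) * Tp, "+")             # (T_out, K, C)
  flat <- outer(flat, (seq_len(B) - 1L) * (Tp * C), "+")       # (T_out, K, C, B)
  idx <- matrix(as.integer(aperm(flat, c(1, 4, 2, 3))), T_out * B, K * C)
  out <- list(idx = idx, starts = starts, T_out = T_out, Tp = Tp)
  .conv_idx_cache[[key]] <- out
  out
}

# Causal 1D convolution. x: (T, Cin, B); W: (K*Cin) x Cout with column-major
# kernel layout (offset k fastest, then input channel); b: Cout or NULL.
# Left zero-padding of K-1 samples makes the kernel causal; with stride s the
# output length is ceiling(T / s).
conv1d_forward <- function(x, W, b, K, stride = 1L, keep_cache = FALSE) {
  d <- dim(x); Tn <- d[1]; C <- d[2]; B <- d[3]
  pad <- K - 1L
  Tp <- Tn + pad
  xpad <- array(0, c(Tp, C, B))
  xpad[pad + seq_len(Tn), , ] <- x
  gi <- conv_gather_idx(Tn, C, B, K, stride)
  T_out <- gi$T_out; starts <- gi$starts
  X_col <- matrix(xpad[gi$idx], nrow(gi$idx), ncol(gi$idx))
  Y <- X_col %*% W
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  y <- aperm(array(Y, c(T_out, B, ncol(W))), c(1, 3, 2))
  cache <- if (keep_cache) {
    list(X_col = X_col, starts = starts, K = K, stride = stride,
         Tn = Tn, C = C, B = B, Tp = Tp, pad = pad, has_bias = !is.null(b))
  } else NULL
  list(y = y, cache = cache)
}

conv1d_backward <- function(dy, cache, W) {
  T_out <- dim(dy)[1]; Cout <- dim(dy)[2]; B <- cache$B
  dY <- matrix(aperm(dy, c(1, 3, 2)), T_out * B, Cout)
  dW <- crossprod(cache$X_col, dY)
  db <- if (cache$has_bias) colSums(dY) else NULL
  dX_col <- tcrossprod(dY, W)                                  # (T_out*B, K*C)
  dxa <- array(dX_col, c(T_out, B, cache$K, cache$C))
  dxpad <- array(0, c(cache$Tp, cache$C, B))
  for (k in seq_len(cache$K)) {
    rows <- cache$starts + k - 1L
    slice <- array(aperm(dxa[, , k, , drop = FALSE], c(1, 4, 2, 3)),
                   c(T_out, cache$C, B))
    dxpad[rows, , ] <- dxpad[rows, , , drop = FALSE] + slice
  }
  dx <- dxpad[cache$pad + seq_len(cache$Tn), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- activations -----------------------------------------------------------

#' Symmetric logarithmic activation
#'
#' `y = sgn(x) * log(|x| + 1)`: odd, monotone, linear near zero and
#' logarithmically compressive for large magnitudes. Used after the learnable
#' filterbank so waveform-scale inputs enter the encoder with a bounded
#' dynamic range.
#'
#' @param x numeric vector/array
#' @return transformed values, same shape
#' @export
symmetric_log <- function(x) sign(x) * log1p(abs(x))

symlog_backward <- function(dy, x) dy / (1 + abs(x))

# Parametric rectifier with one learnable slope per channel (dim 2).
prelu_forward <- function(x, a) {
  a_arr <- array(rep(a, each = dim(x)[1]), dim(x))
  list(y = pmax(x, 0) + a_arr * pmin(x, 0), a_arr = a_arr)
}

prelu_backward <- function(dy, x, a_arr) {
  dx <- dy * ifelse(x > 0, 1, a_arr)
  da <- apply(dy * pmin(x, 0), 2, sum)
  list(dx = dx, da = da)
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

# Softmax over dim 2 of a (T, Nc, M, B) array.
softmax4 <- function(z) {
  zmax <- apply(z, c(1, 3, 4), max)
  ez <- exp(z - aperm(array(zmax, c(dim(z)[1], dim(z)[3], dim(z)[4], dim(z)[2])),
                      c(1, 4, 2, 3)))
  den <- apply(ez, c(1, 3, 4), sum)
  ez / aperm(array(den, c(dim(z)[1], dim(z)[3], dim(z)[4], dim(z)[2])),
             c(1, 4, 2, 3))
}

# ---- learnable sinc filterbank --------------------------------------------

# Band-pass sinc kernels from raw parameters (p_lo, p_bw). Effective
# cut-offs: f1 = clamp(|p_lo|), f2 = clamp(f1 + |p_bw|) below Nyquist.
# Returns the (K x n_f) kernel bank and everything the backward pass needs.
sinc_kernels <- function(p_lo, p_bw, K, rate) {
  nyq <- rate / 2
  f1 <- pmin(pmax(abs(p_lo), 30), nyq - 60)
  f2 <- pmin(f1 + pmax(abs(p_bw), 20), nyq - 1)
  tk <- (seq_len(K) - 1 - (K - 1) / 2) / rate
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(K) - 1) / (K - 1))  # Hamming
  g <- function(f) {
    out <- outer(tk, f, function(t, ff) ifelse(t == 0, 2 * ff,
                                               sin(2 * pi * ff * t) / (pi * t)))
    out
  }
  H <- (g(f2) - g(f1)) * w
  list(H = H, f1 = f1, f2 = f2, tk = tk, w = w,
       clamped_lo = abs(p_lo) <= 30 | abs(p_lo) >= nyq - 60,
       clamped_bw = abs(p_bw) <= 20 | f2 >= nyq - 1,
       sgn_lo = ifelse(p_lo >= 0, 1, -1), sgn_bw = ifelse(p_bw >= 0, 1, -1))
}

# Chain dL/dH (K x n_f) back to the raw cut-off parameters.
sinc_backward <- function(dH, sk) {
  dcos <- function(f) outer(sk$tk, f, function(t, ff) 2 * cos(2 * pi * ff * t))
  df2 <- colSums(dH * dcos(sk$f2) * sk$w)
  df1 <- colSums(dH * (-dcos(sk$f1)) * sk$w)
  # f2 = f1 + |p_bw| so p_lo feels both paths
  dp_lo <- (df1 + df2) * sk$sgn_lo * ifelse(sk$clamped_lo, 0, 1)
  dp_bw <- df2 * sk$sgn_bw * ifelse(sk$clamped_bw, 0, 1)
  list(dp_lo = dp_lo, dp_bw = dp_bw)
}

# Mel-spaced initial cut-offs over a frequency band.
mel_spaced_edges <- function(n, f_lo, f_hi) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  imel(seq(mel(f_lo), mel(f_hi), length.out = n + 1))
}

# ---- parameter-tree helpers ------------------------------------------------

# Model parameters live in nested lists of numeric arrays; these walkers
# apply a function leaf-wise across one or two congruent trees.
tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_sum <- function(f, tree) {
  if (is.list(tree)) sum(vapply(tree, function(x) tree_sum(f, x), numeric(1)))
  else f(tree)
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
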