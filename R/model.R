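# The sound-to-spike-count encoder-decoder. A learnable sinc filterbank and
# symmetric-log front end feed five causal strided convolutions (parametric
# rectifiers) into a 64-channel bottleneck; per-animal linear decoders map
# the bottleneck to the parameters of a per-unit-per-bin count distribution
# (Poisson rate or 5-class categorical). Recording time can enter either at
# the audio rate (concatenated after the front end) or at the bottleneck
# rate (multiplied into the bottleneck), which lets the model absorb slow
# non-stationarity.

#' Model configuration
#'
#' Defaults describe the full-scale architecture: a 48-filter learnable
#' band-pass front end (kernel 64), five 128-filter causal convolutions with
#' kernel 64 and stride 2 (total decimation 2^5 = 32), a 64-filter bottleneck
#' (kernel 64, stride 1), and per-branch 1x1 linear decoders without bias.
#' Input frames are `frame` audio samples plus `context` samples of left
#' context; the context is cropped after the bottleneck (context/32 bins), so
#' a 8,192 + 2,048 sample input yields 256 output bins at 762.9395 Hz.
#' Scaled-down variants for desk experiments override the widths and frame
#' sizes; the stride structure (and hence the 32x decimation) is fixed.
#'
#' @param n_front number of front-end band-pass filters
#' @param front_kernel front-end kernel length in samples
#' @param n_enc encoder filters per layer
#' @param enc_kernel encoder kernel length
#' @param n_enc_layers number of stride-2 encoder layers (5 gives 32x)
#' @param n_bneck bottleneck channels
#' @param bneck_kernel bottleneck kernel length
#' @param context left context in audio samples (divisible by 32)
#' @param frame frame length in audio samples (divisible by 32)
#' @param n_classes 1 (Poisson head) or 5 (categorical head over counts 0-4)
#' @param time_module `"none"`, `"audio"` (audio-rate concatenation),
#'   `"bottleneck"` (simple 1x1 map multiplied into the bottleneck) or
#'   `"bottleneck_complex"` (stacked 1x1 maps)
#' @param time_scale scaling of recording time at the model boundary
#'   (seconds x 1/36,000)
#' @param time_hidden hidden width of the complex time module
#' @param rate audio sampling rate
#' @return a `model_config` list
#' @export
model_config <- function(n_front = 48, front_kernel = 64, n_enc = 128,
                         enc_kernel = 64, n_enc_layers = 5, n_bneck = 64,
                         bneck_kernel = 64, context = 2048, frame = 8192,
                         n_classes = 5, time_module = "none",
                         time_scale = 1 / 36000, time_hidden = 128,
                         rate = audio_rate()) {
  stride_total <- 2^n_enc_layers
  stopifnot(frame %% stride_total == 0, context %% stride_total == 0)
  if (!n_classes %in% c(1L, 5L)) stop("n_classes must be 1 (Poisson) or 5 (categorical)")
  time_module <- match.arg(time_module,
                           c("none", "audio", "bottleneck", "bottleneck_complex"))
  structure(list(n_front = n_front, front_kernel = front_kernel, n_enc = n_enc,
                 enc_kernel = enc_kernel, n_enc_layers = n_enc_layers,
                 stride = 2L, n_bneck = n_bneck, bneck_kernel = bneck_kernel,
                 context = context, frame = frame, n_classes = as.integer(n_classes),
                 time_module = time_module, time_scale = time_scale,
                 time_hidden = time_hidden, rate = rate,
                 stride_total = stride_total),
            class = "model_config")
}

glorot <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout, 0, sqrt(1 / fan)), nin, nout)

#' Build an encoder-decoder model
#'
#' Initializes all parameters reproducibly from `seed`. Front-end cut-offs
#' start mel-spaced over 50 Hz - 12 kHz; parametric-rectifier slopes start at
#' 0.25; convolution weights are scaled-normal.
#'
#' @param cfg a [model_config()]
#' @param units integer vector: number of modelled units per branch (one
#'   entry per animal/branch)
#' @param seed initialization seed
#' @return an object of class `spikecoder_model`
#' @export
build_model <- function(cfg, units = 512L, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"), all(units >= 1))
  with_seed(derive_seed(seed, "init"), {
    edges <- mel_spaced_edges(cfg$n_front, 50, 12000)
    front <- list(p_lo = edges[-(cfg$n_front + 1)],
                  p_bw = diff(edges))
    c_in1 <- if (cfg$time_module == "audio") 2L * cfg$n_front else cfg$n_front
    enc <- vector("list", cfg$n_enc_layers)
    cin <- c_in1
    for (l in seq_len(cfg$n_enc_layers)) {
      enc[[l]] <- list(W = glorot(cfg$enc_kernel * cin, cfg$n_enc, cfg$enc_kernel * cin),
                       b = numeric(cfg$n_enc), a = rep(0.25, cfg$n_enc))
      cin <- cfg$n_enc
    }
    bneck <- list(W = glorot(cfg$bneck_kernel * cfg$n_enc, cfg$n_bneck,
                             cfg$bneck_kernel * cfg$n_enc),
                  b = numeric(cfg$n_bneck), a = rep(0.25, cfg$n_bneck))
    time_audio <- if (cfg$time_module == "audio") {
      list(W = matrix(stats::rnorm(cfg$n_front, 0, 1), 1, cfg$n_front))
    } else NULL
    branches <- lapply(units, function(M) new_branch_params(cfg, M))
    params <- list(front = front, time_audio = time_audio, enc = enc,
                   bneck = bneck, branches = branches)
  })
  structure(list(cfg = cfg, units = as.integer(units), params = params),
            class = "spikecoder_model")
}

new_branch_params <- function(cfg, M) {
  tm <- switch(cfg$time_module,
    none = NULL, audio = NULL,
    bottleneck = list(list(W = matrix(stats::rnorm(cfg$n_bneck, 0, 1), 1, cfg$n_bneck),
                           b = numeric(cfg$n_bneck), a = rep(0.25, cfg$n_bneck))),
    bottleneck_complex = {
      widths <- c(rep(cfg$time_hidden, 3), cfg$n_bneck)
      cin <- 1L
      lapply(widths, function(w) {
        l <- list(W = glorot(cin, w, max(cin, 4)), b = numeric(w), a = rep(0.25, w))
        cin <<- w
        l
      })
    })
  list(time = tm,
       dec = list(W = glorot(cfg$n_bneck, M * cfg$n_classes, cfg$n_bneck)))
}

#' @export
print.spikecoder_model <- function(x, ...) {
  cat(sprintf(paste0("<spikecoder_model> %s head, %d branch(es), time module '%s'\n",
                     "  front %d x %d | encoder %d x (%d filters, kernel %d, stride 2)",
                     " | bottleneck %d\n  frame %d + context %d samples -> %d bins\n"),
              if (x$cfg$n_classes == 1) "Poisson" else "categorical",
              length(x$units), x$cfg$time_module,
              x$cfg$n_front, x$cfg$front_kernel, x$cfg$n_enc_layers, x$cfg$n_enc,
              x$cfg$enc_kernel, x$cfg$n_bneck, x$cfg$frame, x$cfg$context,
              x$cfg$frame %/% x$cfg$stride_total))
  invisible(x)
}

# ---- forward ---------------------------------------------------------------

# sound: (T_in x B) matrix (T_in = frame + context); time_s: NULL, (T_in x B)
# seconds for the audio-rate module, or (T_out x B) seconds (one per output
# bin) for the bottleneck-rate modules. Returns the head distribution, the
# cropped bottleneck, and (when training) the caches for the backward pass.
model_forward <- function(model, sound, time_s = NULL, branch = 1L,
                          training = FALSE) {
  cfg <- model$cfg; P <- model$params
  if (is.vector(sound)) sound <- matrix(sound, ncol = 1)
  T_in <- nrow(sound); B <- ncol(sound)
  if (T_in <= cfg$context || (T_in - cfg$context) %% cfg$stride_total != 0) {
    stop(sprintf(
      "input length %d is not context (%d) + a multiple of %d samples",
      T_in, cfg$context, cfg$stride_total), call. = FALSE)
  }
  if (cfg$time_module != "none" && is.null(time_s)) {
    stop("this model requires a recording-time input", call. = FALSE)
  }
  M <- model$units[branch]
  cache <- list()
  x <- array(sound, c(T_in, 1, B))

  sk <- sinc_kernels(P$front$p_lo, P$front$p_bw, cfg$front_kernel, cfg$rate)
  cv <- conv1d_forward(x, sk$H, NULL, cfg$front_kernel, 1L, keep_cache = training)
  cache$front <- cv$cache; cache$sk <- sk
  pre_sym <- cv$y
  x <- symmetric_log(pre_sym)
  cache$pre_sym <- if (training) pre_sym else NULL

  if (cfg$time_module == "audio") {
    tau <- array(as.matrix(time_s) * cfg$time_scale, c(T_in, 1, B))
    tv <- conv1d_forward(tau, P$time_audio$W, NULL, 1L, 1L, keep_cache = training)
    cache$taudio <- tv$cache
    cache$taudio_pre <- if (training) tv$y else NULL
    tsig <- symmetric_log(tv$y)
    xc <- array(0, c(T_in, dim(x)[2] + dim(tsig)[2], B))
    xc[, seq_len(dim(x)[2]), ] <- x
    xc[, dim(x)[2] + seq_len(dim(tsig)[2]), ] <- tsig
    cache$n_front_ch <- dim(x)[2]
    x <- xc
  }

  cache$enc <- vector("list", cfg$n_enc_layers)
  for (l in seq_len(cfg$n_enc_layers)) {
    cv <- conv1d_forward(x, P$enc[[l]]$W, P$enc[[l]]$b, cfg$enc_kernel, cfg$stride,
                         keep_cache = training)
    pr <- prelu_forward(cv$y, P$enc[[l]]$a)
    cache$enc[[l]] <- if (training) list(conv = cv$cache, pre = cv$y, a_arr = pr$a_arr) else NULL
    x <- pr$y
  }

  cv <- conv1d_forward(x, P$bneck$W, P$bneck$b, cfg$bneck_kernel, 1L,
                       keep_cache = training)
  pr <- prelu_forward(cv$y, P$bneck$a)
  cache$bneck <- if (training) list(conv = cv$cache, pre = cv$y, a_arr = pr$a_arr) else NULL
  x <- pr$y

  crop <- cfg$context %/% cfg$stride_total
  T_full <- dim(x)[1]
  bott <- x[crop + seq_len(T_full - crop), , , drop = FALSE]  # (T_out, n_bneck, B)
  T_out <- dim(bott)[1]
  cache$crop <- crop; cache$T_full <- T_full

  z_in <- bott
  if (cfg$time_module %in% c("bottleneck", "bottleneck_complex")) {
    tau <- array(as.matrix(time_s) * cfg$time_scale, c(T_out, 1, B))
    tmods <- P$branches[[branch]]$time
    cache$tmod <- vector("list", length(tmods))
    h <- tau
    for (l in seq_along(tmods)) {
      cv <- conv1d_forward(h, tmods[[l]]$W, tmods[[l]]$b, 1L, 1L, keep_cache = training)
      pr <- prelu_forward(cv$y, tmods[[l]]$a)
      cache$tmod[[l]] <- if (training) list(conv = cv$cache, pre = cv$y, a_arr = pr$a_arr) else NULL
      h <- pr$y
    }
    cache$tgate <- if (training) h else NULL
    cache$bott_pre_gate <- if (training) bott else NULL
    z_in <- bott * h
  }

  dv <- conv1d_forward(z_in, P$branches[[branch]]$dec$W, NULL, 1L, 1L,
                       keep_cache = training)
  cache$dec <- dv$cache
  z <- dv$y  # (T_out, M*Nc, B)

  if (cfg$n_classes == 1L) {
    lam <- softplus(z)
    dist <- list(kind = "poisson", z = z, lambda = lam)
  } else {
    z4 <- array(z, c(T_out, cfg$n_classes, M, B))
    p <- softmax4(z4)
    dist <- list(kind = "categorical", z = z, prob = p)
  }
  list(dist = dist, bottleneck = bott, T_out = T_out, M = M, B = B,
       cache = if (training) cache else NULL, branch = branch)
}

# Backward pass from dL/dz (same shape as the decoder output z) to a full
# gradient tree congruent with model$params (zeros for other branches).
# branch_only = TRUE stops after the branch-specific parameters (decoder and
# time module), skipping the shared trunk -- used when the encoder is frozen.
model_backward <- function(model, fw, dz, branch_only = FALSE) {
  cfg <- model$cfg; P <- model$params; cache <- fw$cache
  g <- tree_map(function(x) x * 0, P)
  branch <- fw$branch

  bk <- conv1d_backward(dz, cache$dec, P$branches[[branch]]$dec$W)
  g$branches[[branch]]$dec$W <- bk$dW
  dzin <- bk$dx

  if (cfg$time_module %in% c("bottleneck", "bottleneck_complex")) {
    dbott <- dzin * cache$tgate
    dh <- dzin * cache$bott_pre_gate
    tmods <- P$branches[[branch]]$time
    for (l in rev(seq_along(tmods))) {
      pb <- prelu_backward(dh, cache$tmod[[l]]$pre, cache$tmod[[l]]$a_arr)
      g$branches[[branch]]$time[[l]]$a <- pb$da
      cb <- conv1d_backward(pb$dx, cache$tmod[[l]]$conv, tmods[[l]]$W)
      g$branches[[branch]]$time[[l]]$W <- cb$dW
      g$branches[[branch]]$time[[l]]$b <- cb$db
      dh <- cb$dx
    }
  } else {
    dbott <- dzin
  }

  if (branch_only) return(g)

  # undo the crop
  dx <- array(0, c(cache$T_full, cfg$n_bneck, fw$B))
  dx[cache$crop + seq_len(cache$T_full - cache$crop), , ] <- dbott

  pb <- prelu_backward(dx, cache$bneck$pre, cache$bneck$a_arr)
  g$bneck$a <- pb$da
  cb <- conv1d_backward(pb$dx, cache$bneck$conv, P$bneck$W)
  g$bneck$W <- cb$dW; g$bneck$b <- cb$db
  dx <- cb$dx

  for (l in rev(seq_len(cfg$n_enc_layers))) {
    pb <- prelu_backward(dx, cache$enc[[l]]$pre, cache$enc[[l]]$a_arr)
    g$enc[[l]]$a <- pb$da
    cb <- conv1d_backward(pb$dx, cache$enc[[l]]$conv, P$enc[[l]]$W)
    g$enc[[l]]$W <- cb$dW; g$enc[[l]]$b <- cb$db
    dx <- cb$dx
  }

  if (cfg$time_module == "audio") {
    nf <- cache$n_front_ch
    dsound_part <- dx[, seq_len(nf), , drop = FALSE]
    dtsig <- dx[, nf + seq_len(dim(dx)[2] - nf), , drop = FALSE]
    dtau_pre <- symlog_backward(dtsig, cache$taudio_pre)
    cb <- conv1d_backward(dtau_pre, cache$taudio, P$time_audio$W)
    g$time_audio$W <- cb$dW
    dx <- dsound_part
  }

  dpre <- symlog_backward(dx, cache$pre_sym)
  cb <- conv1d_backward(dpre, cache$front, cache$sk$H)
  sb <- sinc_backward(cb$dW, cache$sk)
  g$front$p_lo <- sb$dp_lo
  g$front$p_bw <- sb$dp_bw
  g
}

# Loss + head gradient for one forward pass. R_arr: (T_out, M, B) observed
# counts (clipped 0-4 for the categorical head). Returns summed loss and
# dL/dz ready for model_backward.
head_loss_grad <- function(fw, R_arr, n_classes) {
  if (n_classes == 1L) {
    lam <- fw$dist$lambda
    R3 <- array(R_arr, dim(lam))
    loss <- sum(lam - R3 * log(pmax(lam, 1e-12)))
    dlam <- 1 - R3 / pmax(lam, 1e-12)
    dz <- dlam * sigmoid(fw$dist$z)
    list(loss = loss, dz = dz)
  } else {
    p <- fw$dist$prob  # (T_out, Nc, M, B)
    dm <- dim(p)
    R3 <- pmin(pmax(array(R_arr, c(dm[1], dm[3], dm[4])), 0), dm[2] - 1)
    onehot <- array(0, dm)
    idx_t <- rep(seq_len(dm[1]), times = dm[3] * dm[4])
    idx_m <- rep(rep(seq_len(dm[3]), each = dm[1]), times = dm[4])
    idx_b <- rep(seq_len(dm[4]), each = dm[1] * dm[3])
    onehot[cbind(idx_t, as.vector(R3) + 1L, idx_m, idx_b)] <- 1
    loss <- -sum(onehot * log(pmax(p, 1e-12)))
    dz4 <- p - onehot
    list(loss = loss, dz = array(dz4, c(dm[1], dm[2] * dm[3], dm[4])))
  }
}

# ---- user-facing distribution container ------------------------------------

#' Predicted count distribution
#'
#' Per-unit-per-bin predicted distribution of spike counts: either a Poisson
#' rate matrix (units x bins) or categorical probabilities over counts 0-4
#' (units x bins x 5 array; rows sum to 1).
#'
#' @param kind `"poisson"` or `"categorical"`
#' @param lambda units x bins rate matrix (Poisson)
#' @param prob units x bins x classes probability array (categorical)
#' @return an object of class `count_distribution`
#' @export
count_distribution <- function(kind = c("poisson", "categorical"),
                               lambda = NULL, prob = NULL) {
  kind <- match.arg(kind)
  if (kind == "poisson") {
    stopifnot(!is.null(lambda), all(is.finite(lambda)), all(lambda >= 0))
    if (is.vector(lambda)) lambda <- matrix(lambda, nrow = 1)
    structure(list(kind = kind, lambda = lambda), class = "count_distribution")
  } else {
    stopifnot(!is.null(prob), length(dim(prob)) == 3)
    sums <- apply(prob, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-6)) stop("categorical rows must sum to 1", call. = FALSE)
    structure(list(kind = kind, prob = prob), class = "count_distribution")
  }
}

#' @export
print.count_distribution <- function(x, ...) {
  d <- if (x$kind == "poisson") dim(x$lambda) else dim(x$prob)
  cat(sprintf("<count_distribution> %s, %d units x %d bins\n", x$kind, d[1], d[2]))
  invisible(x)
}

#' @export
dim.count_distribution <- function(x) {
  if (x$kind == "poisson") dim(x$lambda) else dim(x$prob)[1:2]
}

#' Poisson count loss
#'
#' `sum(lambda - R * log(lambda))` over units and bins: the negative Poisson
#' log-likelihood up to the data-dependent constant. Minimized per bin at
#' `lambda = R`.
#'
#' @param lambda a `count_distribution` (Poisson) or rate matrix
#' @param R observed counts, same shape
#' @return summed loss (infinite, with a warning, when `lambda` is 0 at an
#'   observed positive count)
#' @export
poisson_loss <- function(lambda, R) {
  if (inherits(lambda, "count_distribution")) {
    stopifnot(lambda$kind == "poisson"); lambda <- lambda$lambda
  }
  if (inherits(R, "mua_response")) R <- R$counts
  stopifnot(identical(dim(lambda), dim(R)) || length(lambda) == length(R))
  bad <- lambda == 0 & R > 0
  if (any(bad)) {
    warning("zero rate at an observed positive count: infinite loss")
    return(Inf)
  }
  sum(lambda - ifelse(R > 0, R * log(lambda), 0))
}

#' Categorical (cross-entropy) count loss
#'
#' Negative log-probability of the observed count (clipped to 0-4) summed
#' over units and bins, with a one-hot indicator of the observed class.
#'
#' @param p a `count_distribution` (categorical) or units x bins x classes array
#' @param R observed counts (units x bins)
#' @return summed loss (infinite, with a warning, at zero observed-class mass)
#' @export
categorical_loss <- function(p, R) {
  if (inherits(p, "count_distribution")) {
    stopifnot(p$kind == "categorical"); p <- p$prob
  }
  if (inherits(R, "mua_response")) R <- R$counts
  nc <- dim(p)[3]
  Rc <- pmin(pmax(R, 0), nc - 1)
  idx <- cbind(as.vector(row(Rc)), as.vector(col(Rc)), as.vector(Rc) + 1L)
  mass <- p[idx]
  if (any(mass == 0)) {
    warning("zero probability mass at an observed count: infinite loss")
    return(Inf)
  }
  -sum(log(mass))
}

#' Mean log-likelihood of observed counts under a predicted distribution
#'
#' Mean over units and bins of the log-probability mass the model assigns to
#' the observed count (Poisson pmf for the Poisson head; the categorical
#' class probability otherwise).
#'
#' @param p a `count_distribution`
#' @param R observed counts (matrix or `mua_response`)
#' @return mean log-likelihood per unit-bin (`-Inf` with a warning when any
#'   observed count has zero mass)
#' @export
loglik_metric <- function(p, R) {
  if (inherits(R, "mua_response")) R <- R$counts
  if (p$kind == "poisson") {
    ll <- stats::dpois(R, p$lambda, log = TRUE)
    if (any(!is.finite(ll))) warning("zero mass at an observed count")
    mean(ll)
  } else {
    nc <- dim(p$prob)[3]
    Rc <- pmin(pmax(R, 0), nc - 1)
    idx <- cbind(as.vector(row(Rc)), as.vector(col(Rc)), as.vector(Rc) + 1L)
    mass <- p$prob[idx]
    if (any(mass == 0)) {
      warning("zero probability mass at an observed count")
      return(-Inf)
    }
    mean(log(mass))
  }
}

#' Sample a simulated response from a predicted count distribution
#'
#' Independent draws per unit and bin; Poisson draws are clipped at 4 (the
#' count ceiling used throughout). Reproducible from `seed`.
#'
#' @param p a `count_distribution`
#' @param seed RNG seed
#' @param max_count clip value for Poisson draws
#' @return a `mua_response` of sampled counts
#' @export
sample_response <- function(p, seed = 1L, max_count = 4) {
  d <- dim(p)
  counts <- with_seed(derive_seed(seed, "sample_response"), {
    if (p$kind == "poisson") {
      matrix(pmin(stats::rpois(prod(d), as.vector(p$lambda)), max_count), d[1], d[2])
    } else {
      nc <- dim(p$prob)[3]
      pm <- matrix(p$prob, prod(d), nc)
      u <- stats::runif(prod(d))
      cum <- pm %*% upper.tri(diag(nc), diag = TRUE)  # row-wise cumsum
      matrix(rowSums(u > cum) , d[1], d[2])
    }
  })
  mua_response(counts)
}

#' Expected counts of a predicted distribution
#'
#' The per-unit-per-bin expectation: the rate for the Poisson head, `sum(n *
#' p_n)` for the categorical head.
#'
#' @param p a `count_distribution`
#' @return units x bins matrix of expectations
#' @export
expected_counts <- function(p) {
  if (p$kind == "poisson") return(p$lambda)
  d <- dim(p$prob)
  matrix(matrix(p$prob, d[1] * d[2], d[3]) %*% (seq_len(d[3]) - 1), d[1], d[2])
}
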