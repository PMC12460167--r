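# Dataset framing, the training protocol (Adam, halve-on-plateau schedule,
# early stopping), whole-stimulus prediction, and encoder-frozen decoder
# transfer.

#' Bundle a stimulus, its binned response and its recording time
#'
#' One presentation of a sound during a session: the calibrated waveform, the
#' simultaneous binned counts (sample-locked: count bin k covers audio
#' samples 32(k-1)+1 ... 32k), the recording time of the presentation onset
#' in seconds, and the decoder branch (animal) it belongs to.
#'
#' @param stimulus a `sound_stimulus`
#' @param response a `mua_response` (or `NULL` for prediction-only sessions)
#' @param start_time_s recording time of the first sample, seconds
#' @param branch decoder branch index
#' @param id optional stimulus identifier used for train/eval disjointness
#' @export
recording_session <- function(stimulus, response = NULL, start_time_s = 0,
                              branch = 1L, id = NULL) {
  stopifnot(inherits(stimulus, "sound_stimulus"))
  if (!is.null(response)) stopifnot(inherits(response, "mua_response"))
  structure(list(stimulus = stimulus, response = response,
                 start_time_s = start_time_s, branch = as.integer(branch),
                 id = id),
            class = "recording_session")
}

#' Training protocol configuration
#'
#' Adam with a starting learning rate of 4e-4 and batches of 50 frames; the
#' learning rate is halved when the validation loss fails to decrease for two
#' consecutive epochs, and training stops after four such epochs. Ten percent
#' of frames form the validation set.
#'
#' @param batch frames per gradient step
#' @param lr starting learning rate
#' @param lr_patience epochs without validation improvement before halving
#' @param stop_patience epochs without improvement before early stop
#' @param max_epochs hard cap on epochs
#' @param validation validation fraction (0-1)
#' @param seed run-level seed (batching, splits)
#' @export
train_config <- function(batch = 50, lr = 4e-4, lr_patience = 2,
                         stop_patience = 4, max_epochs = 100,
                         validation = 0.10, seed = 1L) {
  stopifnot(validation > 0, validation < 1)
  structure(list(batch = as.integer(batch), lr = lr,
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 max_epochs = as.integer(max_epochs),
                 validation = validation, seed = as.integer(seed)),
            class = "train_config")
}

#' Cut sessions into aligned training frames
#'
#' Non-overlapping frames of `cfg$frame` audio samples with `cfg$context`
#' samples of left context taken from the preceding audio (zero-padded at the
#' session start), paired with the matching `frame/32` count bins and the
#' per-frame recording times. A seeded random fraction of frames (or whole
#' sessions with `split_by = "session"`) is flagged for validation.
#'
#' @param sessions list of [recording_session()] objects
#' @param cfg the [model_config()] that will consume the frames
#' @param validation validation fraction
#' @param split_by `"frame"` or `"session"`
#' @param seed split seed
#' @return a tibble with list-columns `sound` (frame + context samples),
#'   `counts` (units x bins), `t0_s`, plus `branch`, `session`, `frame`, `val`
#' @export
frame_dataset <- function(sessions, cfg, validation = 0.10,
                          split_by = c("frame", "session"), seed = 1L) {
  split_by <- match.arg(split_by)
  stride_total <- cfg$stride_total
  rows <- purrr::imap(sessions, function(ses, si) {
    s <- ses$stimulus$samples
    n_frames <- length(s) %/% cfg$frame
    if (n_frames < 1) stop("session shorter than one frame", call. = FALSE)
    R <- ses$response$counts
    bins_per_frame <- cfg$frame %/% stride_total
    if (!is.null(R) && ncol(R) < n_frames * bins_per_frame) {
      stop("misaligned session: fewer count bins than framed audio requires",
           call. = FALSE)
    }
    purrr::map(seq_len(n_frames), function(k) {
      a0 <- (k - 1) * cfg$frame           # 0-based frame start
      ctx <- numeric(cfg$context)
      avail <- min(cfg$context, a0)
      if (avail > 0) ctx[cfg$context - avail + seq_len(avail)] <- s[a0 - avail + seq_len(avail)]
      sound <- c(ctx, s[a0 + seq_len(cfg$frame)])
      counts <- if (is.null(R)) NULL else
        R[, (k - 1) * bins_per_frame + seq_len(bins_per_frame), drop = FALSE]
      tibble::tibble(
        sound = list(sound), counts = list(counts),
        t0_s = ses$start_time_s + a0 / cfg$rate,
        branch = ses$branch, session = si, frame = k,
        id = if (is.null(ses$id)) NA_character_ else as.character(ses$id))
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  with_seed(derive_seed(seed, "val_split"), {
    if (split_by == "frame") {
      n_val <- round(validation * nrow(out))
      val_idx <- sample.int(nrow(out), n_val)
      out$val <- seq_len(nrow(out)) %in% val_idx
    } else {
      ses_ids <- unique(out$session)
      n_val <- max(1, round(validation * length(ses_ids)))
      vs <- sample(ses_ids, n_val)
      out$val <- out$session %in% vs
    }
  })
  attr(out, "cfg") <- cfg
  out
}

# Recording-time inputs for a batch of frames, in the representation the
# configured time module expects (seconds; scaling happens inside the model).
batch_time_inputs <- function(cfg, t0_s, n_frames) {
  if (cfg$time_module == "none") return(NULL)
  if (cfg$time_module == "audio") {
    T_in <- cfg$frame + cfg$context
    offs <- (seq_len(T_in) - 1 - cfg$context) / cfg$rate
    outer(offs, t0_s, "+") |> pmax(0)
  } else {
    T_out <- cfg$frame %/% cfg$stride_total
    offs <- (seq_len(T_out) - 1) * cfg$stride_total / cfg$rate
    outer(offs, t0_s, "+")
  }
}

assemble_batch <- function(frames, cfg) {
  sound <- do.call(cbind, frames$sound)
  Tb <- cfg$frame %/% cfg$stride_total
  counts <- array(0, c(Tb, nrow(frames$counts[[1]]), nrow(frames)))
  for (i in seq_len(nrow(frames))) counts[, , i] <- t(frames$counts[[i]])
  list(sound = sound, counts = counts,
       tau = batch_time_inputs(cfg, frames$t0_s, nrow(frames)))
}

batch_loss <- function(model, bt, branch, training = FALSE) {
  fw <- model_forward(model, bt$sound, time_s = bt$tau, branch = branch,
                      training = training)
  hl <- head_loss_grad(fw, bt$counts, model$cfg$n_classes)
  denom <- prod(dim(bt$counts))
  list(fw = fw, loss = hl$loss / denom, dz = hl$dz / denom)
}

#' Train a model on a framed dataset
#'
#' Implements the full protocol: Adam updates over seeded shuffled
#' minibatches (each batch drawn within one branch), per-epoch validation
#' loss, learning-rate halving after `lr_patience` epochs without validation
#' improvement, early stopping after `stop_patience`, and restoration of the
#' best-validation weights. Losses are reported per unit-bin.
#'
#' @param model a `spikecoder_model`
#' @param frames a frame tibble from [frame_dataset()] (with a `val` column)
#' @param tcfg a [train_config()]
#' @param trainable optional character: `"branch_only"` freezes everything
#'   except the branch in `branch_filter`
#' @param branch_filter optional integer: train only on frames of this branch
#' @param verbose print per-epoch progress?
#' @return a `spikecoder_fit`: the fitted model plus a history tibble
#' @export
train <- function(model, frames, tcfg = train_config(), trainable = NULL,
                  branch_filter = NULL, verbose = FALSE) {
  cfg <- model$cfg
  if (!is.null(branch_filter)) frames <- dplyr::filter(frames, .data$branch %in% branch_filter)
  tr <- dplyr::filter(frames, !.data$val)
  va <- dplyr::filter(frames, .data$val)
  stopifnot(nrow(tr) > 0, nrow(va) > 0)
  mask <- NULL
  if (identical(trainable, "branch_only")) {
    stopifnot(!is.null(branch_filter))
    mask <- tree_map(function(x) 0, model$params)
    for (b in branch_filter) {
      mask$branches[[b]] <- tree_map(function(x) 1, model$params$branches[[b]])
    }
  }
  state <- adam_init(model$params)
  lr <- tcfg$lr
  best_val <- Inf; best_params <- model$params; bad_epochs <- 0L
  history <- list()
  val_loss_of <- function(m) {
    tot <- 0; n <- 0
    for (b in unique(va$branch)) {
      vb <- dplyr::filter(va, .data$branch == b)
      for (i0 in seq(1, nrow(vb), by = tcfg$batch)) {
        sub <- vb[i0:min(i0 + tcfg$batch - 1, nrow(vb)), ]
        bt <- assemble_batch(sub, cfg)
        bl <- batch_loss(m, bt, b, training = FALSE)
        k <- prod(dim(bt$counts))
        tot <- tot + bl$loss * k; n <- n + k
      }
    }
    tot / n
  }
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- with_seed(derive_seed(tcfg$seed, paste0("epoch", epoch)),
                     sample.int(nrow(tr)))
    trs <- tr[ord, ]
    train_tot <- 0; train_n <- 0
    for (b in unique(trs$branch)) {
      tb <- dplyr::filter(trs, .data$branch == b)
      for (i0 in seq(1, nrow(tb), by = tcfg$batch)) {
        sub <- tb[i0:min(i0 + tcfg$batch - 1, nrow(tb)), ]
        bt <- assemble_batch(sub, cfg)
        bl <- batch_loss(model, bt, b, training = TRUE)
        if (!is.finite(bl$loss)) {
          stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
               call. = FALSE)
        }
        g <- model_backward(model, bl$fw, bl$dz,
                            branch_only = identical(trainable, "branch_only"))
        if (!is.null(mask)) g <- tree_map2(function(gg, mm) gg * mm, g, mask)
        st <- adam_step(model$params, g, state, lr)
        model$params <- st$params; state <- st$state
        k <- prod(dim(bt$counts))
        train_tot <- train_tot + bl$loss * k; train_n <- train_n + k
      }
    }
    vl <- val_loss_of(model)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = train_tot / train_n,
                                       val_loss = vl, lr = lr)
    if (verbose) {
      message(sprintf("epoch %d: train %.5f val %.5f lr %.2e", epoch,
                      train_tot / train_n, vl, lr))
    }
    if (vl < best_val - 1e-9) {
      best_val <- vl; best_params <- model$params; bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs %% tcfg$lr_patience == 0L) lr <- lr / 2
      if (bad_epochs >= tcfg$stop_patience) break
    }
  }
  model$params <- best_params
  structure(list(model = model, history = dplyr::bind_rows(history),
                 best_val = best_val, tcfg = tcfg),
            class = "spikecoder_fit")
}

#' @export
print.spikecoder_fit <- function(x, ...) {
  cat(sprintf("<spikecoder_fit> %d epochs, best validation loss %.5f/unit-bin\n",
              nrow(x$history), x$best_val))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.spikecoder_fit <- function(x, ...) x$history

#' Tidiers for fitted models
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary (epochs run, best validation loss, final learning rate).
#'
#' @param x a `spikecoder_fit`
#' @param ... unused
#' @name tidiers
#' @export
glance.spikecoder_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_val_loss = x$best_val,
                 final_lr = x$history$lr[nrow(x$history)],
                 head = if (x$model$cfg$n_classes == 1) "poisson" else "categorical",
                 time_module = x$model$cfg$time_module)
}

#' Predict the count distribution for a whole stimulus
#'
#' Splits the sound into consecutive frames (true left context from the
#' preceding audio, zeros at the start), runs the model, and stitches the
#' per-frame distributions into one units x bins distribution. With
#' `fixed_time_s` set, the recording-time input is pinned to that constant
#' (stationary mode); otherwise it follows `start_time_s` plus elapsed time.
#'
#' @param model a `spikecoder_model` or `spikecoder_fit`
#' @param stimulus a `sound_stimulus` (or numeric waveform at the model rate)
#' @param start_time_s recording time of the stimulus onset, seconds
#' @param branch decoder branch
#' @param fixed_time_s optional constant recording time (stationary mode)
#' @param batch frames per forward pass
#' @return a `count_distribution`; the cropped bottleneck response (channels
#'   x bins) is attached as attribute `"bottleneck"`
#' @export
predict_distribution <- function(model, stimulus, start_time_s = 0,
                                 branch = 1L, fixed_time_s = NULL, batch = 8L) {
  if (inherits(model, "spikecoder_fit")) model <- model$model
  cfg <- model$cfg
  s <- if (inherits(stimulus, "sound_stimulus")) stimulus$samples else as.numeric(stimulus)
  n_bins_true <- floor(length(s) / cfg$stride_total)
  n_frames <- ceiling(length(s) / cfg$frame)
  s_pad <- c(s, numeric(n_frames * cfg$frame - length(s)))
  M <- model$units[branch]
  Tb <- cfg$frame %/% cfg$stride_total
  lam <- NULL; pr <- NULL
  bneck <- matrix(0, cfg$n_bneck, n_frames * Tb)
  for (i0 in seq(1, n_frames, by = batch)) {
    ks <- i0:min(i0 + batch - 1, n_frames)
    sound <- vapply(ks, function(k) {
      a0 <- (k - 1) * cfg$frame
      ctx <- numeric(cfg$context)
      avail <- min(cfg$context, a0)
      if (avail > 0) ctx[cfg$context - avail + seq_len(avail)] <- s_pad[a0 - avail + seq_len(avail)]
      c(ctx, s_pad[a0 + seq_len(cfg$frame)])
    }, numeric(cfg$frame + cfg$context))
    t0s <- start_time_s + (ks - 1) * cfg$frame / cfg$rate
    tau <- if (!is.null(fixed_time_s) && cfg$time_module != "none") {
      dims <- if (cfg$time_module == "audio") cfg$frame + cfg$context else Tb
      matrix(fixed_time_s, dims, length(ks))
    } else batch_time_inputs(cfg, t0s, length(ks))
    fw <- model_forward(model, sound, time_s = tau, branch = branch)
    for (j in seq_along(ks)) {
      cols <- (ks[j] - 1) * Tb + seq_len(Tb)
      bneck[, cols] <- t(fw$bottleneck[, , j])
      if (cfg$n_classes == 1L) {
        if (is.null(lam)) lam <- matrix(0, M, n_frames * Tb)
        lam[, cols] <- t(fw$dist$lambda[, , j])
      } else {
        if (is.null(pr)) pr <- array(0, c(M, n_frames * Tb, cfg$n_classes))
        pr[, cols, ] <- array(aperm(fw$dist$prob[, , , j, drop = FALSE],
                                    c(3, 1, 2, 4)), c(M, Tb, cfg$n_classes))
      }
    }
  }
  out <- if (cfg$n_classes == 1L) {
    count_distribution("poisson", lambda = lam[, seq_len(n_bins_true), drop = FALSE])
  } else {
    count_distribution("categorical", prob = pr[, seq_len(n_bins_true), , drop = FALSE])
  }
  attr(out, "bottleneck") <- bneck[, seq_len(n_bins_true), drop = FALSE]
  out
}

#' Transfer a frozen encoder to a new animal
#'
#' Appends a fresh decoder branch (and, for time-variant models, a fresh
#' time module) to a trained model, freezes every shared parameter, and fits
#' only the new branch on the new animal's frames. The encoder weights are
#' byte-identical before and after.
#'
#' @param fit a trained `spikecoder_fit` (or `spikecoder_model`)
#' @param frames frame tibble for the new animal (its `branch` column must
#'   equal the new branch index, i.e. `length(model$units) + 1`)
#' @param n_units number of units of the new animal
#' @param tcfg a [train_config()]
#' @param init_seed seed for the new branch's initialization
#' @param verbose print per-epoch progress?
#' @return a `spikecoder_fit` whose model contains the added branch
#' @export
transfer_decoder <- function(fit, frames, n_units, tcfg = train_config(),
                             init_seed = 1L, verbose = FALSE) {
  model <- if (inherits(fit, "spikecoder_fit")) fit$model else fit
  new_idx <- length(model$units) + 1L
  with_seed(derive_seed(init_seed, "transfer_branch"), {
    model$params$branches[[new_idx]] <- new_branch_params(model$cfg, n_units)
  })
  model$units <- c(model$units, as.integer(n_units))
  train(model, frames, tcfg, trainable = "branch_only",
        branch_filter = new_idx, verbose = verbose)
}
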