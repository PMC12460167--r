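# Evaluation metrics: overall performance (RMSE, log-likelihood),
# noise-corrected predictive power (explainable correlation and variance),
# coherence, Fano factors, modulation transfer functions, tuning summaries,
# the non-stationarity index, bottleneck PCA and bootstrap CIs.

#' Pair of responses to successive identical-stimulus trials
#'
#' Holds the recorded responses of two successive trials, and optionally the
#' model predictions for each trial: sampled responses (`rhat1`, `rhat2`)
#' and/or predicted distributions (`dist1`, `dist2`).
#'
#' @param r1,r2 units x bins count matrices (or `mua_response`) of equal shape
#' @param rhat1,rhat2 optional sampled predicted responses, same shape
#' @param dist1,dist2 optional `count_distribution` objects, same shape
#' @export
trial_pair <- function(r1, r2, rhat1 = NULL, rhat2 = NULL,
                       dist1 = NULL, dist2 = NULL) {
  as_mat <- function(x) if (inherits(x, "mua_response")) x$counts else x
  r1 <- as_mat(r1); r2 <- as_mat(r2)
  rhat1 <- as_mat(rhat1); rhat2 <- as_mat(rhat2)
  stopifnot(identical(dim(r1), dim(r2)))
  for (x in list(rhat1, rhat2)) if (!is.null(x)) stopifnot(identical(dim(x), dim(r1)))
  structure(list(r1 = r1, r2 = r2, rhat1 = rhat1, rhat2 = rhat2,
                 dist1 = dist1, dist2 = dist2),
            class = "trial_pair")
}

#' Root-mean-square error between recorded and predicted counts
#'
#' `sqrt(mean((R - Rhat)^2))` over all units and bins.
#'
#' @param R,Rhat equal-shaped count matrices (or `mua_response`)
#' @return scalar RMSE
#' @export
rmse_metric <- function(R, Rhat) {
  if (inherits(R, "mua_response")) R <- R$counts
  if (inherits(Rhat, "mua_response")) Rhat <- Rhat$counts
  if (length(R) == 0) stop("empty input", call. = FALSE)
  stopifnot(identical(dim(R), dim(Rhat)))
  sqrt(mean((R - Rhat)^2))
}

# Population variance (divide by n): used wherever the noise-corrected
# variance fractions are assembled so that degenerate fixtures return exact
# percentages.
pvar <- function(x) mean((x - mean(x))^2)

#' Fraction of explainable correlation explained (%)
#'
#' `100/2 * (rho(R1, Rhat1) + rho(R2, Rhat2)) / rho(R1, R2)` with responses
#' flattened across units and bins. Per-unit mode computes the same quantity
#' over time only. Values above 100% can occur when the prediction
#' out-correlates the trial pair (high non-stationarity); a non-positive
#' trial-pair correlation makes the quantity undefined (`NA` with a warning).
#'
#' @param pair a [trial_pair()] with sampled predictions
#' @param per_unit compute per unit instead of flattened?
#' @return percentage (scalar, or per-unit vector)
#' @export
correlation_explained <- function(pair, per_unit = FALSE) {
  stopifnot(inherits(pair, "trial_pair"), !is.null(pair$rhat1), !is.null(pair$rhat2))
  one <- function(r1, r2, p1, p2) {
    den <- stats::cor(r1, r2)
    if (!is.finite(den) || den <= 0) {
      warning("non-positive trial-pair correlation: correlation explained undefined")
      return(NA_real_)
    }
    50 * (stats::cor(r1, p1) + stats::cor(r2, p2)) / den
  }
  if (!per_unit) {
    one(as.vector(pair$r1), as.vector(pair$r2),
        as.vector(pair$rhat1), as.vector(pair$rhat2))
  } else {
    vapply(seq_len(nrow(pair$r1)), function(m) {
      suppressWarnings(one(pair$r1[m, ], pair$r2[m, ], pair$rhat1[m, ], pair$rhat2[m, ]))
    }, numeric(1))
  }
}

#' Fraction of explainable variance explained (%)
#'
#' Noise-corrected variance fraction: the squared error between recordings
#' and the distribution expectations, corrected by the trial-to-trial noise
#' variance `0.5 * Var[R1 - R2]`, relative to the explainable (signal)
#' variance. Negative values occur when the prediction error exceeds the
#' explainable variance. Variances are computed on flattened responses
#' (per-unit mode: across time only).
#'
#' @param pair a [trial_pair()] carrying `dist1`/`dist2` (expectations are
#'   taken via [expected_counts()]) or pre-computed expectation matrices in
#'   `rhat1`/`rhat2`
#' @param per_unit compute per unit instead of flattened?
#' @return percentage (scalar, or per-unit vector)
#' @export
variance_explained <- function(pair, per_unit = FALSE) {
  stopifnot(inherits(pair, "trial_pair"))
  E1 <- if (!is.null(pair$dist1)) expected_counts(pair$dist1) else pair$rhat1
  E2 <- if (!is.null(pair$dist2)) expected_counts(pair$dist2) else pair$rhat2
  stopifnot(!is.null(E1), !is.null(E2))
  one <- function(r1, r2, e1, e2) {
    s_noise <- 0.5 * pvar(r1 - r2)
    num <- 0.5 * mean((r1 - e1)^2) + 0.5 * mean((r2 - e2)^2) - s_noise
    den <- 0.5 * (pvar(r1) + pvar(r2)) - s_noise
    if (!is.finite(den) || den <= 0) {
      warning("non-positive explainable variance: variance explained undefined")
      return(NA_real_)
    }
    100 * (1 - num / den)
  }
  if (!per_unit) {
    one(as.vector(pair$r1), as.vector(pair$r2), as.vector(E1), as.vector(E2))
  } else {
    vapply(seq_len(nrow(pair$r1)), function(m) {
      suppressWarnings(one(pair$r1[m, ], pair$r2[m, ], E1[m, ], E2[m, ]))
    }, numeric(1))
  }
}

#' Unit-averaged magnitude-squared coherence
#'
#' Welch-style estimate over the time axis: non-overlapping Hann-windowed
#' segments of `n_bins` bins per unit, cross- and auto-spectral densities
#' averaged across segments, `|G12|^2 / (G1 G2)` per unit and frequency,
#' averaged over units. With `which = "prediction"` the coherence between
#' prediction and recording is computed for each trial pairing and averaged.
#' Frequencies with zero power in either signal are masked (`NA`).
#'
#' @param pair a [trial_pair()]
#' @param n_bins segment length (frequency bins)
#' @param which `"trials"` (R1 vs R2) or `"prediction"` (Rhat vs R)
#' @param rate bin rate in Hz
#' @return tibble with `freq_hz` and `coherence` (length `n_bins %/% 2 + 1`)
#' @export
coherence_metric <- function(pair, n_bins = 763, which = c("trials", "prediction"),
                             rate = bin_rate()) {
  which <- match.arg(which)
  coh_xy <- function(X, Y) {
    # X, Y: units x bins
    n_seg <- ncol(X) %/% n_bins
    if (n_seg < 1) stop("fewer bins than one coherence segment", call. = FALSE)
    w <- 0.5 * (1 - cos(2 * pi * seq_len(n_bins) / (n_bins + 1)))  # Hann
    acc <- matrix(0, nrow(X), n_bins %/% 2 + 1)
    for (m in seq_len(nrow(X))) {
      G12 <- complex(real = numeric(n_bins), imaginary = numeric(n_bins))
      G1 <- numeric(n_bins); G2 <- numeric(n_bins)
      for (s in seq_len(n_seg)) {
        idx <- (s - 1) * n_bins + seq_len(n_bins)
        Fx <- stats::fft(X[m, idx] * w)
        Fy <- stats::fft(Y[m, idx] * w)
        G12 <- G12 + Fx * Conj(Fy)
        G1 <- G1 + Mod(Fx)^2
        G2 <- G2 + Mod(Fy)^2
      }
      c_m <- Mod(G12)^2 / (G1 * G2)
      c_m[G1 == 0 | G2 == 0] <- NA_real_
      acc[m, ] <- c_m[seq_len(ncol(acc))]
    }
    colMeans(acc, na.rm = TRUE)
  }
  coh <- if (which == "trials") {
    coh_xy(pair$r1, pair$r2)
  } else {
    stopifnot(!is.null(pair$rhat1), !is.null(pair$rhat2))
    (coh_xy(pair$rhat1, pair$r1) + coh_xy(pair$rhat2, pair$r2)) / 2
  }
  tibble::tibble(freq_hz = (seq_along(coh) - 1) * rate / n_bins, coherence = coh)
}

#' Per-unit Fano factors from repeated trials
#'
#' Across-trial variance-to-mean ratio per bin (population variance),
#' averaged over the analysis-window bins; bins with zero mean count are
#' masked. Values below 1 indicate sub-Poisson (underdispersed) counts.
#'
#' @param R units x bins x trials array (>= 2 trials)
#' @param window bin indices of the analysis window (default: all bins)
#' @return tibble with `unit`, `fano`, `n_bins_used`
#' @export
fano_factor <- function(R, window = NULL) {
  stopifnot(length(dim(R)) == 3, dim(R)[3] >= 2)
  if (is.null(window)) window <- seq_len(dim(R)[2])
  mu <- apply(R[, window, , drop = FALSE], c(1, 2), mean)
  vv <- apply(R[, window, , drop = FALSE], c(1, 2), function(x) mean((x - mean(x))^2))
  fano <- vapply(seq_len(nrow(mu)), function(m) {
    ok <- mu[m, ] > 0
    if (!any(ok)) return(NA_real_)
    mean(vv[m, ok] / mu[m, ok])
  }, numeric(1))
  used <- rowSums(mu > 0)
  tibble::tibble(unit = seq_len(nrow(mu)), fano = fano, n_bins_used = used)
}

#' Synchrony (modulation transfer function component)
#'
#' Ratio of the modulation-frequency component to the d.c. component of the
#' magnitude-squared spectrum of the trial-averaged response, per unit, over
#' an analysis window of `n_bins` bins starting at `onset_s + window_start`.
#' A constant response has synchrony 0 at every modulation frequency; the
#' measure is invariant to multiplicative rate scaling.
#'
#' @param R units x bins matrix (trial-averaged response, bin 1 at time 0)
#' @param mod_freqs modulation frequencies in Hz
#' @param onset_s stimulus onset in seconds
#' @param window_start analysis-window start after onset (s)
#' @param n_bins window length in bins (the FFT uses the same number)
#' @param rate bin rate in Hz
#' @return tibble with `unit`, `mod_freq_hz`, `synchrony` (`NA` at zero d.c.)
#' @export
synchrony_mtf <- function(R, mod_freqs, onset_s = 0, window_start = 0.0079,
                          n_bins = 763, rate = bin_rate()) {
  if (inherits(R, "mua_response")) R <- R$counts
  b0 <- max(1L, ceiling((onset_s + window_start) * rate - 1e-9))
  stopifnot(b0 + n_bins - 1 <= ncol(R))
  idx <- b0 + seq_len(n_bins) - 1
  res <- rate / n_bins
  kbin <- round(mod_freqs / res) + 1L
  purrr::map_dfr(seq_len(nrow(R)), function(m) {
    X <- stats::fft(R[m, idx])
    dc <- Mod(X[1])^2
    sync <- if (dc == 0) {
      warning("zero d.c. component: synchrony undefined")
      rep(NA_real_, length(mod_freqs))
    } else Mod(X[kbin])^2 / dc
    tibble::tibble(unit = m, mod_freq_hz = mod_freqs, synchrony = sync)
  })
}

#' Windowed mean activity per annotated stimulus condition
#'
#' For every annotated event with a label in `labels`, counts inside
#' `[onset + window[1], onset + window[2])` are averaged per unit, then
#' averaged across repeats of the same (frequency, level) condition. This is
#' the workhorse behind frequency-response areas (7.9-50 ms window),
#' rate-intensity functions, masked-probe rates (7.9-20 ms) and
#' context-enhancement summaries (7.9-100 ms).
#'
#' @param resp a `mua_response` aligned to the stimulus
#' @param annotations annotation tibble of the stimulus
#' @param window analysis window relative to event onset, seconds
#' @param labels annotation labels to include
#' @return tibble with `unit`, `label`, `freq_hz`, `level_db`, `mean_count`
#'   (mean per bin), `n_events`
#' @export
tuning_summary <- function(resp, annotations, window = c(0.0079, 0.05),
                           labels = NULL) {
  stopifnot(inherits(resp, "mua_response"))
  ev <- annotations
  if (!is.null(labels)) ev <- dplyr::filter(ev, .data$label %in% labels)
  stopifnot(nrow(ev) >= 1)
  rate <- resp$bin_rate_hz; Tn <- ncol(resp$counts)
  per_event <- purrr::map_dfr(seq_len(nrow(ev)), function(i) {
    b <- window_bins(ev$onset_s[i] + window[1], ev$onset_s[i] + window[2], rate)
    if (length(b) == 0 || max(b) > Tn) {
      stop("analysis window extends beyond the recording", call. = FALSE)
    }
    tibble::tibble(unit = seq_len(nrow(resp$counts)),
                   label = ev$label[i], freq_hz = ev$freq_hz[i],
                   level_db = ev$level_db[i],
                   mean_count = rowMeans(resp$counts[, b, drop = FALSE]))
  })
  per_event |>
    dplyr::group_by(.data$unit, .data$label, .data$freq_hz, .data$level_db) |>
    dplyr::summarise(n_events = dplyr::n(),
                     mean_count = mean(.data$mean_count), .groups = "drop")
}

#' Non-stationarity index
#'
#' Absolute difference between the mean covariance of flattened responses on
#' successive trials and on trials recorded far apart: `|mean(cov(e1, e2),
#' cov(l1, l2)) - mean(cov(e1, l1), cov(e2, l2))|`. A stationary recording
#' has an index near zero; slow gain drift inflates it.
#'
#' @param early list/`trial_pair` of two successive early-session responses
#' @param late list/`trial_pair` of two successive late-session responses
#' @return scalar index
#' @export
nonstationarity_index <- function(early, late) {
  get2 <- function(p) {
    if (inherits(p, "trial_pair")) list(p$r1, p$r2)
    else lapply(p[1:2], function(x) if (inherits(x, "mua_response")) x$counts else x)
  }
  e <- get2(early); l <- get2(late)
  stopifnot(identical(dim(e[[1]]), dim(e[[2]])), identical(dim(l[[1]]), dim(l[[2]])),
            identical(dim(e[[1]]), dim(l[[1]])))
  cv <- function(a, b) stats::cov(as.vector(a), as.vector(b))
  successive <- mean(c(cv(e[[1]], e[[2]]), cv(l[[1]], l[[2]])))
  separated <- mean(c(cv(e[[1]], l[[1]]), cv(e[[2]], l[[2]])))
  abs(successive - separated)
}

#' PCA of the normalized bottleneck response
#'
#' The silence-referenced bottleneck (`(r - mean response to silence) /
#' scale`, default scale -500 to match the scale and sign of binned counts)
#' is decomposed per sound into principal components over time; variance
#' fractions per component are reported.
#'
#' @param bneck channels x bins bottleneck response for one sound
#' @param silence_response channels x bins response to silence (or a
#'   per-channel mean vector)
#' @param scale divisor applied after mean subtraction
#' @return list with `scores` (bins x components), `loadings`,
#'   `variance_fraction`, and the normalized response `normalized`
#' @export
bottleneck_pca <- function(bneck, silence_response, scale = -500) {
  stopifnot(is.matrix(bneck))
  mu <- if (is.matrix(silence_response)) rowMeans(silence_response) else silence_response
  stopifnot(length(mu) == nrow(bneck))
  norm <- (bneck - mu) / scale
  if (ncol(norm) < nrow(norm)) {
    stop("fewer time bins than channels: PCA underdetermined", call. = FALSE)
  }
  pc <- stats::prcomp(t(norm), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = vf,
       normalized = norm)
}

#' Bootstrap summary of a per-unit metric
#'
#' Median and percentile 95% CI over bootstrap resamples drawn across units.
#'
#' @param values per-unit metric values (`NA`s dropped with a count)
#' @param n_boot number of bootstrap resamples
#' @param seed RNG seed
#' @param stat summary statistic applied to each resample
#' @return one-row tibble: `value` (stat of the observed units),
#'   `boot_median`, `ci_lo`, `ci_hi`, `n_units`, `n_masked`
#' @export
bootstrap_metric <- function(values, n_boot = 1000, seed = 1L, stat = stats::median) {
  n_masked <- sum(is.na(values))
  v <- values[!is.na(values)]
  stopifnot(length(v) >= 1)
  bs <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(i) stat(sample(v, length(v), replace = TRUE)),
           numeric(1))
  })
  qs <- stats::quantile(bs, c(0.025, 0.5, 0.975), names = FALSE)
  tibble::tibble(value = stat(v), boot_median = qs[2], ci_lo = qs[1],
                 ci_hi = qs[3], n_units = length(v), n_masked = n_masked)
}
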