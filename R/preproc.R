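# Neural preprocessing: raw traces -> binned multi-unit activity (MUA),
# characteristic-frequency estimation, and unit quality control.

#' Construct a binned multi-unit response
#'
#' Counts are integers 0-4 per unit per bin; the canonical bin spans exactly
#' 32 audio samples (1/762.9395 s), keeping count bins sample-locked to the
#' waveform.
#'
#' @param counts units x bins integer matrix (a vector is taken as one unit)
#' @param bin_rate_hz bin rate in Hz
#' @param t0_s recording time of the first bin, in seconds
#' @param units optional tibble of per-unit metadata (`unit`, `cf_hz`,
#'   `animal`, `signal_corr`, ...)
#' @return an object of class `mua_response`
#' @export
mua_response <- function(counts, bin_rate_hz = bin_rate(), t0_s = 0, units = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  storage.mode(counts) <- "double"
  stopifnot(nrow(counts) >= 1)
  if (is.null(units)) units <- tibble::tibble(unit = seq_len(nrow(counts)))
  structure(list(counts = counts, bin_rate_hz = bin_rate_hz, t0_s = t0_s,
                 units = tibble::as_tibble(units)),
            class = "mua_response")
}

#' @export
print.mua_response <- function(x, ...) {
  cat(sprintf("<mua_response> %d units x %d bins @ %.4f Hz (t0 = %.1f s)\n",
              nrow(x$counts), ncol(x$counts), x$bin_rate_hz, x$t0_s))
  invisible(x)
}

#' @export
dim.mua_response <- function(x) dim(x$counts)

#' Extract binned multi-unit activity from a raw trace
#'
#' Each channel is band-pass filtered (zero-phase 4th-order Butterworth), the
#' background-noise SD is estimated robustly as the median absolute
#' deviation / 0.6745, positive-going crossings of `thresh_sd` SDs are
#' counted per bin, and counts are clipped at `max_count`. The pre-clip
#' fraction of counts above the clip value is reported per unit in the
#' `clip_frac` metadata column.
#'
#' @param trace numeric vector (one channel) or channels x samples matrix
#' @param rate trace sampling rate in Hz (20 kHz for the standard protocol)
#' @param band band-pass cut-off frequencies in Hz
#' @param thresh_sd detection threshold in noise SDs
#' @param bin_s bin width in seconds
#' @param max_count clip value for per-bin counts
#' @return a `mua_response` (one unit per channel)
#' @export
extract_mua <- function(trace, rate = 20000, band = c(700, 5000),
                        thresh_sd = 3.5, bin_s = bin_width(), max_count = 4) {
  if (is.vector(trace)) trace <- matrix(trace, nrow = 1)
  stopifnot_finite(trace, "trace")
  n <- ncol(trace)
  n_bins <- ceiling(n / rate / bin_s - 1e-9)
  bin_of <- pmin(floor((seq_len(n) - 1) / rate / bin_s) + 1L, n_bins)
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  counts <- matrix(0, nrow(trace), n_bins)
  clip_frac <- numeric(nrow(trace))
  for (ch in seq_len(nrow(trace))) {
    x <- trace[ch, ]
    if (stats::sd(x) == 0) {
      if (all(x == x[1]) && x[1] == 0) next  # silent channel: zero counts
      stop("zero-SD trace: cannot estimate the noise floor", call. = FALSE)
    }
    y <- signal::filtfilt(bf, x)
    sd_noise <- stats::mad(y, constant = 1 / 0.6745)  # MAD / 0.6745
    if (sd_noise == 0) stop("zero-SD trace after filtering", call. = FALSE)
    thr <- thresh_sd * sd_noise
    crossing <- which(y[-1] > thr & y[-length(y)] <= thr) + 1L
    raw <- tabulate(bin_of[crossing], nbins = n_bins)
    clip_frac[ch] <- mean(raw > max_count)
    counts[ch, ] <- pmin(raw, max_count)
  }
  mua_response(counts, bin_rate_hz = 1 / bin_s,
               units = tibble::tibble(unit = seq_len(nrow(trace)),
                                      clip_frac = clip_frac))
}

#' Exact Poisson significance threshold
#'
#' Smallest count k whose upper tail probability P(X >= k) under a Poisson
#' rate `mu` falls below `alpha`. At mu = 1 and alpha = 1e-4 the threshold
#' is 7 (P(X >= 7) ~ 8.3e-5).
#'
#' @param mu Poisson rate over the counting window
#' @param alpha tail probability
#' @return integer threshold count
#' @export
poisson_sig_threshold <- function(mu, alpha = 1e-4) {
  k <- stats::qpois(alpha, mu, lower.tail = FALSE)  # P(X > k) < alpha
  while (k > 0 && stats::ppois(k - 1 - 1, mu, lower.tail = FALSE) < alpha) k <- k - 1
  while (stats::ppois(k - 1, mu, lower.tail = FALSE) >= alpha) k <- k + 1
  as.integer(k)
}

#' Estimate characteristic frequencies from a tone battery response
#'
#' For every (frequency, level) cell the tone-evoked counts inside the
#' analysis window are summed over repeats. A cell is significant when the
#' summed count reaches the exact Poisson upper-tail threshold at `alpha`,
#' with rate `max(silence_rate, 1/8)` per single-repeat window scaled by the
#' number of repeats. The characteristic frequency (CF) of a unit is the
#' frequency of the significant cell at the lowest level; among equally
#' significant cells at that level the largest count wins, remaining ties go
#' to the lowest frequency. Units with no significant cell get `NA`.
#'
#' @param resp a `mua_response` recorded during the battery
#' @param annotations the battery's annotation tibble (label `"tone"`)
#' @param window analysis window relative to tone onset, seconds `[a, b)`
#' @param silence_rate per-unit expected counts per single-repeat window in
#'   silence; `NULL` estimates it from the bins not covered by any analysis
#'   window
#' @param alpha significance level of the exact Poisson test
#' @return tibble with `unit`, `cf_hz`, `cf_level_db`
#' @export
estimate_cf <- function(resp, annotations, window = c(0.0079, 0.05),
                        silence_rate = NULL, alpha = 1e-4) {
  stopifnot(inherits(resp, "mua_response"))
  tones <- dplyr::filter(annotations, .data$label == "tone")
  stopifnot(nrow(tones) >= 1)
  rate <- resp$bin_rate_hz
  M <- nrow(resp$counts); Tn <- ncol(resp$counts)
  evoked_bins <- lapply(seq_len(nrow(tones)), function(i) {
    b <- window_bins(tones$onset_s[i] + window[1], tones$onset_s[i] + window[2], rate)
    b[b >= 1 & b <= Tn]
  })
  n_window_bins <- length(window_bins(window[1], window[2], rate))
  if (is.null(silence_rate)) {
    used <- unique(unlist(evoked_bins))
    # anything within a tone presentation (onset..onset+duration+window) is excluded
    near <- unique(unlist(lapply(seq_len(nrow(tones)), function(i) {
      b <- window_bins(tones$onset_s[i], tones$onset_s[i] + tones$duration_s[i] + window[2], rate)
      b[b >= 1 & b <= Tn]
    })))
    silent <- setdiff(seq_len(Tn), union(used, near))
    silence_rate <- if (length(silent)) {
      rowMeans(resp$counts[, silent, drop = FALSE]) * n_window_bins
    } else rep(0, M)
  }
  silence_rate <- rep_len(silence_rate, M)
  cells <- tones |>
    dplyr::mutate(.idx = dplyr::row_number()) |>
    dplyr::group_by(.data$freq_hz, .data$level_db)
  key <- dplyr::group_keys(cells)
  idx_by_cell <- dplyr::group_rows(cells)
  counts_cell <- matrix(0, M, nrow(key))  # summed over repeats and window bins
  reps_cell <- integer(nrow(key))
  for (j in seq_len(nrow(key))) {
    rows <- idx_by_cell[[j]]
    reps_cell[j] <- length(rows)
    bins <- unlist(evoked_bins[rows])
    if (length(bins)) counts_cell[, j] <- rowSums(resp$counts[, bins, drop = FALSE])
  }
  out <- purrr::map_dfr(seq_len(M), function(m) {
    mu <- pmax(silence_rate[m], 1 / 8) * reps_cell
    thr <- vapply(mu, poisson_sig_threshold, integer(1), alpha = alpha)
    sig <- counts_cell[m, ] >= thr
    if (!any(sig)) {
      return(tibble::tibble(unit = m, cf_hz = NA_real_, cf_level_db = NA_real_))
    }
    lev_min <- min(key$level_db[sig])
    cand <- which(sig & key$level_db == lev_min)
    cand <- cand[order(-counts_cell[m, cand], key$freq_hz[cand])]
    tibble::tibble(unit = m, cf_hz = key$freq_hz[cand[1]], cf_level_db = lev_min)
  })
  out
}

#' Unit quality control from repeated broadband-noise trials
#'
#' Signal correlation is the per-unit Pearson correlation of binned counts
#' across two trials of the identical stimulus; units at or above the
#' threshold are flagged for inclusion. Zero-variance units have undefined
#' correlation and are excluded.
#'
#' @param trial1,trial2 `mua_response` objects of identical shape
#' @param threshold inclusion threshold (inclusive)
#' @return tibble with `unit`, `signal_correlation`, `include`
#' @export
qc_units <- function(trial1, trial2, threshold = 0.2) {
  stopifnot(identical(dim(trial1$counts), dim(trial2$counts)))
  M <- nrow(trial1$counts)
  r <- vapply(seq_len(M), function(m) {
    a <- trial1$counts[m, ]; b <- trial2$counts[m, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  tibble::tibble(unit = seq_len(M), signal_correlation = r,
                 include = !is.na(r) & r >= threshold)
}
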