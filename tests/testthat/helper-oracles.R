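# Independent naive implementation of the MUA extraction chain: plain-R
# robust SD, an explicit per-sample crossing loop, and floor-based binning.
# Shared by the preprocessing and acceptance suites.
naive_mua <- function(x, rate = 20000, band = c(700, 5000), thresh_sd = 3.5,
                      bin_s = bin_width(), max_count = 4) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  med <- stats::median(y)
  mad_raw <- stats::median(abs(y - med))
  thr <- thresh_sd * mad_raw / 0.6745
  n_bins <- ceiling(length(y) / rate / bin_s - 1e-9)
  counts <- numeric(n_bins)
  for (i in 2:length(y)) {
    if (y[i] > thr && y[i - 1] <= thr) {
      b <- min(floor((i - 1) / rate / bin_s) + 1, n_bins)
      counts[b] <- counts[b] + 1
    }
  }
  pmin(counts, max_count)
}
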