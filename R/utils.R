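# Shared constants and small helpers.

#' Canonical audio sampling rate (samples/s)
#'
#' All stimulus synthesis and modelling operates at 24,414.0625 Hz, the rate
#' at which spike-count bins (32 audio samples each) stay sample-locked to the
#' waveform.
#' @export
audio_rate <- function() 24414.0625

#' Spike-count bin rate (bins/s)
#'
#' One count bin spans exactly 32 audio samples: 24,414.0625 / 32 =
#' 762.9395 Hz, i.e. a bin width of about 1.31 ms.
#' @export
bin_rate <- function() audio_rate() / 32

#' Width of one spike-count bin in seconds
#' @export
bin_width <- function() 32 / audio_rate()

# Local RNG scope: run `expr` under a seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a run-level seed and a stream label, staying below
# 2^31 so the result is a valid R integer.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Convert a time window to spike-count bin indices
#'
#' A half-open window `[a, b)` in seconds maps to the 1-based bins
#' `ceiling(a * rate)` through `ceiling(b * rate) - 1`. This single rule is
#' used for every analysis window in the package; a 7.9-ms window start at
#' the canonical bin rate excludes exactly the first 6 bins.
#'
#' @param a,b window start and end in seconds (half-open `[a, b)`)
#' @param rate bin rate in Hz
#' @return integer vector of bin indices (possibly empty)
#' @export
window_bins <- function(a, b, rate = bin_rate()) {
  lo <- max(1L, ceiling(a * rate - 1e-9))
  hi <- ceiling(b * rate - 1e-9) - 1L
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

rms <- function(x) sqrt(mean(x^2))

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
}
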