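# Synthetic inferior-colliculus population: a controllable ground-truth
# simulator that turns calibrated sound into bounded, underdispersed,
# optionally non-stationary multi-unit counts. It emulates the response
# statistics the modelling framework targets (tonotopic frequency tuning,
# sigmoidal rate-intensity functions, divisive adaptation producing forward
# masking and dynamic-range shifts, slow multiplicative gain drift, and
# sub-Poisson count dispersion) without claiming biophysical realism.

#' Create a synthetic midbrain population
#'
#' Unit parameters are drawn reproducibly from `seed`: characteristic
#' frequencies log-uniform over 300 Hz - 12 kHz (sorted, i.e. tonotopic
#' order), Gaussian-on-log-frequency tuning widths, sigmoidal rate-intensity
#' thresholds and dynamic ranges, bounded maximum rates (counts/bin <= 4),
#' a divisive-adaptation time constant, per-trial gain jitter controlling
#' trial-to-trial reliability, and a session-long multiplicative gain-drift
#' profile.
#'
#' @param M number of units
#' @param seed RNG seed
#' @param config optional overrides: `cf_range` (Hz), `width_oct` (range),
#'   `threshold_db` (range), `dyn_range_db` (range), `max_rate` (range,
#'   counts/bin), `spont_rate` (counts/bin), `adapt_tau_s`,
#'   `adapt_strength`, `jitter_sd`, `poisson_mix` (0 = pure
#'   binomial(4, r/4) counts, 1 = pure clipped Poisson), and `drift` (list
#'   with `type` in none/linear/exponential/sinusoidal, `magnitude` in
#'   [0, 1], `session_h`, `period_h`)
#' @return a `synthetic_population` tibble (one row per unit) with the
#'   shared settings in attributes
#' @export
make_population <- function(M, seed = 1L, config = list()) {
  stopifnot(M >= 1)
  cfg <- utils::modifyList(list(
    cf_range = c(300, 12000), width_oct = c(0.3, 0.8),
    threshold_db = c(15, 55), dyn_range_db = c(20, 40),
    max_rate = c(1.5, 3.5), spont_rate = 0.02,
    adapt_tau_s = 0.1, adapt_strength = 0.8, jitter_sd = 0.1,
    poisson_mix = 0,
    drift = list(type = "none", magnitude = 0, session_h = 12, period_h = 4)
  ), config)
  pop <- with_seed(derive_seed(seed, "population"), {
    cf <- sort(exp(stats::runif(M, log(cfg$cf_range[1]), log(cfg$cf_range[2]))))
    tibble::tibble(
      unit = seq_len(M),
      cf_hz = cf,
      width_oct = stats::runif(M, cfg$width_oct[1], cfg$width_oct[2]),
      threshold_db = stats::runif(M, cfg$threshold_db[1], cfg$threshold_db[2]),
      dyn_range_db = stats::runif(M, cfg$dyn_range_db[1], cfg$dyn_range_db[2]),
      max_rate = stats::runif(M, cfg$max_rate[1], cfg$max_rate[2])
    )
  })
  attr(pop, "config") <- cfg
  class(pop) <- c("synthetic_population", class(pop))
  pop
}

#' @export
`[.synthetic_population` <- function(x, ...) {
  out <- NextMethod()
  attr(out, "config") <- attr(x, "config")
  class(out) <- class(x)
  out
}

drift_gain <- function(t_s, drift) {
  session_s <- drift$session_h * 3600
  x <- pmin(pmax(t_s / session_s, 0), 1)
  switch(drift$type,
    none = rep(1, length(t_s)),
    linear = 1 - drift$magnitude * x,
    exponential = (1 - drift$magnitude) + drift$magnitude * exp(-3 * x),
    sinusoidal = 1 - drift$magnitude / 2 *
      (1 - cos(2 * pi * t_s / (drift$period_h * 3600))),
    stop("unknown drift type: ", drift$type))
}

# Per-unit band level (dB SPL) per count bin: STFT power weighted by each
# unit's Gaussian-on-log-frequency tuning curve, referenced to the
# calibration convention (tone-correct scaling).
unit_band_levels <- function(pop, stimulus, convention = calibration_convention()) {
  P <- stft_power(stimulus$samples, 512, 32, stimulus$rate, align = "causal")
  f <- attr(P, "freq_hz")
  keep <- f > 0
  P <- P[keep, , drop = FALSE]; f <- f[keep]
  W <- outer(seq_len(nrow(pop)), seq_along(f), function(u, k) {
    exp(-0.5 * (log2(f[k] / pop$cf_hz[u]) / pop$width_oct[u])^2)
  })
  bp <- W %*% P
  convention$level_ref + 10 * log10(bp / convention$rms_ref^2 + 1e-12)
}

#' Simulate binned counts of a synthetic population
#'
#' Pipeline per trial: band level at each unit's CF (Gaussian weighting on a
#' log-frequency axis) -> divisive adaptation applied to the band amplitude
#' with exponential memory (a gain-control stage, subtractive on the dB
#' axis, which shifts rate-intensity functions toward the prevailing level
#' and produces forward-masking-like suppression) -> sigmoidal
#' rate-intensity function (threshold, dynamic range, bounded maximum rate
#' plus spontaneous floor) -> multiplicative gain drift evaluated at the
#' recording time -> per-trial log-normal gain jitter -> counts drawn as
#' binomial(4, rate/4) (mean = rate, Fano = 1 - rate/4, bounded in 0..4),
#' optionally mixed with clipped Poisson draws.
#'
#' @param pop a [make_population()] tibble
#' @param stimulus a calibrated `sound_stimulus` at the canonical rate
#' @param rec_time recording time (s) of each trial onset; length `trials`
#'   values are recycled
#' @param trials number of trials
#' @param seed RNG seed
#' @return list of `mua_response` objects, one per trial (units x bins)
#' @export
simulate_counts <- function(pop, stimulus, rec_time = 0, trials = 1, seed = 1L) {
  stopifnot(inherits(pop, "synthetic_population"),
            inherits(stimulus, "sound_stimulus"))
  if (any(stimulus$samples != 0) && !is.finite(stimulus$level_db_spl) &&
      !any(is.finite(stimulus$annotations$level_db))) {
    stop("uncalibrated stimulus: no level metadata", call. = FALSE)
  }
  cfg <- attr(pop, "config")
  M <- nrow(pop)
  L <- unit_band_levels(pop, stimulus)
  Tn <- ncol(L)
  dt <- bin_width()
  if (cfg$adapt_strength > 0) {
    # gain control on the band amplitude with exponential memory: divisive
    # in pressure, hence subtractive in dB. Shifts rate-intensity functions
    # toward the prevailing stimulus level and yields forward masking.
    alpha <- dt / cfg$adapt_tau_s
    amp <- 10^((L - 50) / 20)  # band amplitude re 50 dB SPL
    A <- numeric(M)
    for (t in seq_len(Tn)) {
      L[, t] <- L[, t] - 20 * log10(1 + cfg$adapt_strength * A)
      A <- A + alpha * (amp[, t] - A)
    }
  }
  k_slope <- 2 * log(9) / pop$dyn_range_db
  mid <- pop$threshold_db + pop$dyn_range_db / 2
  r_ad <- cfg$spont_rate + (pop$max_rate - cfg$spont_rate) /
    (1 + exp(-k_slope * (L - mid)))
  rec_time <- rep_len(rec_time, trials)
  bin_t <- (seq_len(Tn) - 1) * dt
  out <- vector("list", trials)
  for (tr in seq_len(trials)) {
    gd <- drift_gain(rec_time[tr] + bin_t, cfg$drift)
    r <- sweep(r_ad, 2, gd, `*`)
    with_seed(derive_seed(seed, paste0("trial", tr)), {
      gj <- exp(stats::rnorm(M, 0, cfg$jitter_sd) - cfg$jitter_sd^2 / 2)
      r <- pmin(pmax(r * gj, 0), 4)
      counts <- matrix(stats::rbinom(M * Tn, 4, as.vector(r) / 4), M, Tn)
      if (cfg$poisson_mix > 0) {
        use_pois <- matrix(stats::runif(M * Tn) < cfg$poisson_mix, M, Tn)
        cp <- matrix(pmin(stats::rpois(M * Tn, as.vector(r)), 4), M, Tn)
        counts[use_pois] <- cp[use_pois]
      }
    })
    out[[tr]] <- mua_response(counts, t0_s = rec_time[tr],
                              units = tibble::tibble(unit = pop$unit,
                                                     cf_hz = pop$cf_hz))
  }
  out
}

#' Simulate a raw extracellular trace with known ground truth
#'
#' A 20-kHz trace built as Gaussian background noise plus biphasic spike
#' waveforms placed at event times drawn from the simulated counts of a
#' small unit group (<= 10 units per channel). The returned ground-truth
#' bin counts let threshold-crossing extraction be validated exactly.
#'
#' @param pop a `synthetic_population` subset (<= 10 units)
#' @param stimulus a calibrated `sound_stimulus`
#' @param seed RNG seed
#' @param rate trace sampling rate in Hz
#' @param noise_sd background-noise SD
#' @param spike_amp spike peak amplitude in units of `noise_sd`
#' @return list with `trace` (numeric), `rate`, `truth` (summed events per
#'   canonical count bin), and the per-unit simulated counts
#' @export
simulate_raw_trace <- function(pop, stimulus, seed = 1L, rate = 20000,
                               noise_sd = 1, spike_amp = 10) {
  stopifnot(nrow(pop) <= 10)
  counts <- simulate_counts(pop, stimulus, trials = 1,
                            seed = derive_seed(seed, "trace_counts"))[[1]]
  Tn <- ncol(counts$counts)
  n <- ceiling(Tn * bin_width() * rate)
  # biphasic template ~1 ms: positive lobe then undershoot
  tt <- seq(-0.4e-3, 0.6e-3, by = 1 / rate)
  template <- exp(-((tt - 0e-3) / 0.12e-3)^2) - 0.5 * exp(-((tt - 0.25e-3) / 0.2e-3)^2)
  template <- template / max(template) * spike_amp * noise_sd
  with_seed(derive_seed(seed, "trace"), {
    trace <- stats::rnorm(n, 0, noise_sd)
    truth <- numeric(Tn)
    for (m in seq_len(nrow(counts$counts))) {
      bins <- which(counts$counts[m, ] > 0)
      for (b in bins) {
        k <- counts$counts[m, b]
        truth[b] <- truth[b] + k
        t0 <- (b - 1) * bin_width() + stats::runif(k, 0.05, 0.7) * bin_width()
        for (t0i in t0) {
          i0 <- round(t0i * rate)
          idx <- i0 + seq_along(template)
          ok <- idx >= 1 & idx <= n
          trace[idx[ok]] <- trace[idx[ok]] + template[ok]
        }
      }
    }
  })
  list(trace = trace, rate = rate, truth = truth, counts = counts)
}
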