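# Calibrated stimulus synthesis: tone batteries, dynamic moving ripples,
# high-probability-region (HPR) noise sequences, AM noise, forward-masking and
# context-enhancement complexes, speech processing and SNR mixing.
#
# Every generator is a pure function of its arguments and seed; identical
# calls yield bit-identical waveforms.

#' Construct a sound stimulus
#'
#' A `sound_stimulus` holds pressure-proportional samples at a known rate,
#' an optional calibrated sound level, and a tibble of labelled events
#' (tone onsets, burst levels, probe positions, ...).
#'
#' @param samples numeric vector of finite amplitudes
#' @param rate sampling rate in samples/s
#' @param level_db_spl calibrated level in dB SPL, or `NA` when the stimulus
#'   mixes several per-event levels
#' @param annotations tibble with at least `onset_s`, `duration_s`, `label`
#' @return an object of class `sound_stimulus`
#' @export
sound_stimulus <- function(samples, rate = audio_rate(), level_db_spl = NA_real_,
                           annotations = empty_annotations()) {
  stopifnot(rate > 0)
  stopifnot_finite(samples, "samples")
  structure(
    list(samples = as.numeric(samples), rate = rate,
         level_db_spl = level_db_spl,
         annotations = tibble::as_tibble(annotations)),
    class = "sound_stimulus"
  )
}

empty_annotations <- function() {
  tibble::tibble(onset_s = numeric(0), duration_s = numeric(0),
                 label = character(0), freq_hz = numeric(0),
                 level_db = numeric(0))
}

#' @export
print.sound_stimulus <- function(x, ...) {
  cat(sprintf("<sound_stimulus> %d samples @ %.4f Hz (%.3f s)",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  if (is.finite(x$level_db_spl)) cat(sprintf(", %.1f dB SPL", x$level_db_spl))
  cat(sprintf(", %d annotations\n", nrow(x$annotations)))
  invisible(x)
}

#' @export
length.sound_stimulus <- function(x) length(x$samples)

#' RMS-to-level calibration convention
#'
#' Sound level is defined operationally: a waveform with RMS amplitude
#' `rms_ref` is at `level_ref` dB SPL, and level scales as 20 log10 of RMS.
#' The canonical convention ties RMS 0.04 to 94 dB SPL.
#'
#' @param rms_ref reference RMS amplitude (> 0)
#' @param level_ref reference level in dB SPL
#' @export
calibration_convention <- function(rms_ref = 0.04, level_ref = 94) {
  stopifnot(rms_ref > 0)
  structure(list(rms_ref = rms_ref, level_ref = level_ref),
            class = "calibration_convention")
}

#' Sound level of a waveform under a calibration convention
#'
#' @param x a `sound_stimulus` or numeric vector
#' @param convention a [calibration_convention()]
#' @return level in dB SPL
#' @export
sound_level <- function(x, convention = calibration_convention()) {
  s <- if (inherits(x, "sound_stimulus")) x$samples else as.numeric(x)
  r <- rms(s)
  if (r == 0) stop("cannot measure the level of an all-zero waveform", call. = FALSE)
  convention$level_ref + 20 * log10(r / convention$rms_ref)
}

#' Calibrate a waveform to a target sound level
#'
#' Rescales the waveform so its RMS equals
#' `rms_ref * 10^((target - level_ref)/20)` and records the level.
#'
#' @param waveform numeric vector or `sound_stimulus`
#' @param target target level in dB SPL
#' @param convention a [calibration_convention()]
#' @param rate sampling rate, used when `waveform` is a bare vector
#' @return a calibrated `sound_stimulus`
#' @export
calibrate_level <- function(waveform, target, convention = calibration_convention(),
                            rate = audio_rate()) {
  stopifnot(is.finite(target))
  if (inherits(waveform, "sound_stimulus")) {
    s <- waveform$samples; rate <- waveform$rate; ann <- waveform$annotations
  } else {
    s <- as.numeric(waveform); ann <- empty_annotations()
  }
  r <- rms(s)
  if (r == 0) stop("calibration impossible: waveform has zero RMS", call. = FALSE)
  target_rms <- convention$rms_ref * 10^((target - convention$level_ref) / 20)
  sound_stimulus(s * (target_rms / r), rate = rate, level_db_spl = target,
                 annotations = ann)
}

#' Octave-stepped frequency grid with printed-endpoint honouring
#'
#' Generates `f_lo * 2^(k*step)` for k = 0, 1, ... while the value stays at or
#' below `f_hi` (with 1e-9 relative slack). When the printed upper endpoint
#' misses the lattice by less than 0.5% it is appended, so the printed
#' extremes of standard batteries are reproduced.
#'
#' @param f_lo,f_hi grid extremes in Hz
#' @param step spacing in octaves
#' @return increasing numeric vector of frequencies
#' @export
octave_grid <- function(f_lo, f_hi, step) {
  stopifnot(f_lo > 0, f_hi > f_lo, step > 0)
  kmax <- floor(log2(f_hi / f_lo) / step + 1e-9)
  f <- f_lo * 2^(seq(0, kmax) * step)
  last <- f[length(f)]
  # a printed endpoint within 10 ppm of the lattice is the lattice point,
  # merely rounded; a genuine off-lattice printed extreme (< 0.5% away) is
  # appended so printed battery extremes are reproduced
  if (f_hi / last - 1 > 1e-5 && f_hi / last - 1 < 0.005) f <- c(f, f_hi)
  f
}

#' Tone/level presentation grid
#'
#' @param frequencies Hz, strictly increasing
#' @param levels dB SPL
#' @param duration tone duration in s (ramps included)
#' @param ramp cosine ramp duration in s
#' @param gap inter-tone silence in s
#' @param repeats presentations per (frequency, level) cell
#' @param order_seed seed for the randomized presentation order
#' @export
stimulus_grid <- function(frequencies, levels, duration = 0.05, ramp = 0.01,
                          gap = 0.075, repeats = 1, order_seed = 1L) {
  stopifnot(all(diff(frequencies) > 0), repeats >= 1)
  structure(list(frequencies = frequencies, levels = levels,
                 duration = duration, ramp = ramp, gap = gap,
                 repeats = as.integer(repeats), order_seed = as.integer(order_seed)),
            class = "stimulus_grid")
}

# Raised-cosine on/off envelope; ramp time counts inside the duration.
cosine_ramp_envelope <- function(n, ramp_s, rate) {
  nr <- round(ramp_s * rate)
  env <- rep(1, n)
  if (nr > 0) {
    t <- seq_len(nr)
    up <- 0.5 * (1 - cos(pi * (t - 0.5) / nr))
    env[t] <- up
    env[n - nr + t] <- rev(up)
  }
  env
}

# Pure tone at a calibrated level; amplitude A gives RMS A/sqrt(2).
ramped_tone <- function(freq, dur, level, ramp, rate, convention) {
  n <- round(dur * rate)
  amp <- sqrt(2) * convention$rms_ref * 10^((level - convention$level_ref) / 20)
  tt <- (seq_len(n) - 1) / rate
  amp * sin(2 * pi * freq * tt) * cosine_ramp_envelope(n, ramp, rate)
}

#' Synthesize a randomized tone battery (FRA / CF grid)
#'
#' Concatenates ramped pure tones over a frequency x level grid in a seeded
#' random order, with inter-tone silence. Each tone is annotated with its
#' frequency, level and onset; used downstream for frequency-response areas
#' and characteristic-frequency estimation.
#'
#' @param grid a [stimulus_grid()]
#' @param seed presentation-order seed (defaults to the grid's `order_seed`)
#' @param rate sampling rate
#' @param convention calibration convention
#' @return a `sound_stimulus` with one annotation row per tone
#' @export
synth_tone_battery <- function(grid, seed = grid$order_seed, rate = audio_rate(),
                               convention = calibration_convention()) {
  if (grid$ramp > grid$duration / 2) {
    stop("invalid ramp: ramp must not exceed half the tone duration", call. = FALSE)
  }
  cells <- tidyr::expand_grid(freq_hz = grid$frequencies, level_db = grid$levels,
                              rep = seq_len(grid$repeats))
  ord <- with_seed(derive_seed(seed, "tone_order"), sample.int(nrow(cells)))
  cells <- cells[ord, ]
  n_tone <- round(grid$duration * rate)
  n_gap <- round(grid$gap * rate)
  n_trial <- n_tone + n_gap
  out <- numeric(nrow(cells) * n_trial)
  for (i in seq_len(nrow(cells))) {
    s0 <- (i - 1) * n_trial
    out[s0 + seq_len(n_tone)] <-
      ramped_tone(cells$freq_hz[i], grid$duration, cells$level_db[i],
                  grid$ramp, rate, convention)
  }
  ann <- tibble::tibble(
    onset_s = (seq_len(nrow(cells)) - 1) * n_trial / rate,
    duration_s = grid$duration,
    label = "tone",
    freq_hz = cells$freq_hz,
    level_db = cells$level_db
  )
  sound_stimulus(out, rate = rate, annotations = ann)
}

# Piecewise-linear random trajectory in [lo, hi], control points every
# `knot_s` seconds, for slowly varying modulation rates.
random_trajectory <- function(n, rate, lo, hi, knot_s = 0.5) {
  nk <- max(2L, ceiling(n / rate / knot_s) + 1L)
  knots <- stats::runif(nk, lo, hi)
  stats::approx(seq(0, n - 1, length.out = nk), knots, xout = seq_len(n) - 1)$y
}

#' Synthesize a dynamic moving ripple
#'
#' A series of sustained sinusoids at `carrier_step`-octave spacing between
#' `f_lo` and `f_hi` with random phases, jointly amplitude-modulated so the
#' instantaneous temporal modulation rate spans `am_range` (Hz), the
#' instantaneous spectral density spans `fm_range` (cycles/octave), and the
#' modulation depth is `depth` dB.
#'
#' @param f_lo,f_hi lowest/highest carrier frequency in Hz
#' @param carrier_step carrier spacing in octaves
#' @param am_range length-2 range of temporal modulation rates in Hz
#' @param fm_range length-2 range of spectral modulation densities in cyc/oct
#' @param depth modulation depth in dB
#' @param duration duration in s
#' @param seed RNG seed (phases and modulation trajectories)
#' @param rate sampling rate
#' @param level optional calibration level in dB SPL
#' @return a `sound_stimulus`
#' @export
synth_moving_ripple <- function(f_lo, f_hi, carrier_step = 0.02,
                                am_range = c(0, 10), fm_range = c(0, 4),
                                depth = 50, duration = 1, seed = 1L,
                                rate = audio_rate(), level = NULL) {
  if (!(f_lo < f_hi)) stop("f_lo must be below f_hi", call. = FALSE)
  if (f_hi > rate / 2) stop("aliasing: f_hi exceeds the Nyquist frequency", call. = FALSE)
  carriers <- octave_grid(f_lo, f_hi, carrier_step)
  n <- round(duration * rate)
  with_seed(derive_seed(seed, "ripple"), {
    phases <- stats::runif(length(carriers), 0, 2 * pi)
    am <- random_trajectory(n, rate, am_range[1], am_range[2])
    fm <- random_trajectory(n, rate, fm_range[1], fm_range[2])
  })
  phase_t <- 2 * pi * cumsum(am) / rate  # integrated temporal modulation
  tt <- (seq_len(n) - 1) / rate
  x_oct <- log2(carriers / f_lo)
  out <- numeric(n)
  for (i in seq_along(carriers)) {
    a_db <- 0.5 * depth * (sin(phase_t + 2 * pi * fm * x_oct[i]) - 1)
    out <- out + 10^(a_db / 20) * sin(2 * pi * carriers[i] * tt + phases[i])
  }
  stim <- sound_stimulus(out, rate = rate)
  if (!is.null(level)) stim <- calibrate_level(stim, level) else stim
}

#' Synthesize a high-probability-region (HPR) noise-burst sequence
#'
#' Concatenated Gaussian noise bursts whose levels are drawn from an
#' integer-dB grid: every level inside the HPR (a `hpr_range`-dB window
#' centred on `hpr_center`, endpoints included) appears `hpr_draws` times and
#' every other level `other_draws` times, in seeded random order. With
#' `hpr_center = NULL` all levels appear `other_draws` times (uniform
#' baseline). No silence is inserted between bursts unless `gap > 0`.
#'
#' @param level_min,level_max,step level grid in dB SPL
#' @param hpr_center HPR centre in dB SPL, or `NULL` for the uniform baseline
#' @param hpr_range HPR width in dB (12 dB = 13 integer levels inclusive)
#' @param hpr_draws,other_draws draws per level inside/outside the HPR
#' @param burst_dur burst duration in s
#' @param gap inter-burst silence in s
#' @param seed RNG seed (order and noise)
#' @param rate sampling rate
#' @param convention calibration convention
#' @return a `sound_stimulus` with one annotation row per burst
#' @export
synth_hpr_sequence <- function(level_min = 21, level_max = 96, step = 1,
                               hpr_center = 39, hpr_range = 12,
                               hpr_draws = 20, other_draws = 1,
                               burst_dur = 0.05, gap = 0, seed = 1L,
                               rate = audio_rate(),
                               convention = calibration_convention()) {
  levels <- seq(level_min, level_max, by = step)
  if (!is.null(hpr_center)) {
    if (hpr_center - hpr_range / 2 < level_min || hpr_center + hpr_range / 2 > level_max) {
      stop("invalid HPR: the high-probability region falls outside the level range",
           call. = FALSE)
    }
    in_hpr <- levels >= hpr_center - hpr_range / 2 - 1e-9 &
      levels <= hpr_center + hpr_range / 2 + 1e-9
  } else {
    in_hpr <- rep(FALSE, length(levels))
  }
  draws <- ifelse(in_hpr, hpr_draws, other_draws)
  burst_levels <- rep(levels, times = draws)
  n_burst <- round(burst_dur * rate)
  n_gap <- round(gap * rate)
  with_seed(derive_seed(seed, "hpr"), {
    burst_levels <- burst_levels[sample.int(length(burst_levels))]
    out <- numeric(length(burst_levels) * (n_burst + n_gap))
    for (i in seq_along(burst_levels)) {
      z <- stats::rnorm(n_burst)
      tr <- convention$rms_ref * 10^((burst_levels[i] - convention$level_ref) / 20)
      out[(i - 1) * (n_burst + n_gap) + seq_len(n_burst)] <- z * (tr / rms(z))
    }
  })
  ann <- tibble::tibble(
    onset_s = (seq_along(burst_levels) - 1) * (n_burst + n_gap) / rate,
    duration_s = burst_dur, label = "noise_burst",
    freq_hz = NA_real_, level_db = burst_levels
  )
  sound_stimulus(out, rate = rate, annotations = ann)
}

# Band-limited Gaussian noise via brick-wall FFT filtering.
band_noise <- function(n, f_lo, f_hi, rate) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, n - 1) * rate / n
  f <- pmin(f, rate - f)  # fold to physical frequency
  X[f < f_lo | f > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Synthesize amplitude-modulated band-limited noise
#'
#' One-octave (by default) band of Gaussian noise with 4-ms cosine ramps,
#' multiplied by a sinusoidal or raised-sine-N envelope at the given
#' modulation frequency and depth.
#'
#' @param center band centre frequency in Hz
#' @param bandwidth band width in octaves
#' @param mod_freq modulation frequency in Hz (0 disables modulation)
#' @param envelope `"sinusoid"` or `"raised-sine-N"` (e.g. `"raised-sine-32"`)
#' @param depth modulation depth as a fraction (1 = 100%)
#' @param duration duration in s
#' @param level calibration level in dB SPL (or `NULL`)
#' @param seed RNG seed for the noise carrier
#' @param ramp ramp duration in s
#' @param rate sampling rate
#' @return a `sound_stimulus`
#' @export
synth_am_noise <- function(center, bandwidth = 1, mod_freq = 0,
                           envelope = "sinusoid", depth = 1, duration = 1,
                           level = NULL, seed = 1L, ramp = 0.004,
                           rate = audio_rate()) {
  f_lo <- center / 2^(bandwidth / 2)
  f_hi <- center * 2^(bandwidth / 2)
  if (f_hi > rate / 2) stop("band exceeds the Nyquist frequency", call. = FALSE)
  if (mod_freq >= rate / 2) stop("modulation frequency exceeds the Nyquist frequency",
                                 call. = FALSE)
  n <- round(duration * rate)
  noise <- with_seed(derive_seed(seed, "am_noise"), band_noise(n, f_lo, f_hi, rate))
  tt <- (seq_len(n) - 1) / rate
  env <- rep(1, n)
  if (mod_freq > 0 && depth > 0) {
    if (identical(envelope, "sinusoid")) {
      env <- 1 - depth * cos(2 * pi * mod_freq * tt)
    } else if (grepl("^raised-sine-\\d+$", envelope)) {
      N <- as.numeric(sub("^raised-sine-", "", envelope))
      stopifnot(N >= 1)
      env <- (1 - depth) + depth * ((1 - cos(2 * pi * mod_freq * tt)) / 2)^N
    } else {
      stop("unknown envelope type: ", envelope, call. = FALSE)
    }
  }
  out <- noise * env * cosine_ramp_envelope(n, ramp, rate)
  stim <- sound_stimulus(out, rate = rate)
  if (!is.null(level)) calibrate_level(stim, level) else stim
}

#' Synthesize a forward-masking trial sequence
#'
#' For each probe level: an optional 200-ms masker tone, a 10-ms silent gap,
#' then a 20-ms probe tone at the same frequency, followed by inter-trial
#' silence. All tones carry 10-ms cosine ramps. Probe onsets are annotated so
#' the 7.9-20-ms analysis window can be placed downstream.
#'
#' @param probe_freq probe (and masker) frequency in Hz
#' @param probe_levels probe levels in dB SPL
#' @param masker_level masker level in dB SPL, or `NULL` for unmasked trials
#' @param masker_dur,probe_dur tone durations in s
#' @param gap masker-offset to probe-onset silence in s
#' @param isi inter-trial silence in s
#' @param ramp cosine ramp duration in s
#' @param rate sampling rate
#' @param convention calibration convention
#' @return a `sound_stimulus` annotated with masker and probe events
#' @export
synth_forward_masking <- function(probe_freq, probe_levels,
                                  masker_level = NULL, masker_dur = 0.2,
                                  probe_dur = 0.02, gap = 0.01, isi = 0.48,
                                  ramp = 0.01, rate = audio_rate(),
                                  convention = calibration_convention()) {
  stopifnot(gap >= 0)
  n_mask <- if (is.null(masker_level)) 0L else round(masker_dur * rate)
  n_gap <- round(gap * rate)
  n_probe <- round(probe_dur * rate)
  n_isi <- round(isi * rate)
  n_trial <- n_mask + n_gap + n_probe + n_isi
  out <- numeric(length(probe_levels) * n_trial)
  ann <- list()
  for (i in seq_along(probe_levels)) {
    s0 <- (i - 1) * n_trial
    if (!is.null(masker_level)) {
      out[s0 + seq_len(n_mask)] <-
        ramped_tone(probe_freq, masker_dur, masker_level, ramp, rate, convention)
      ann[[length(ann) + 1]] <- tibble::tibble(
        onset_s = s0 / rate, duration_s = masker_dur, label = "masker",
        freq_hz = probe_freq, level_db = masker_level)
    }
    out[s0 + n_mask + n_gap + seq_len(n_probe)] <-
      ramped_tone(probe_freq, probe_dur, probe_levels[i], ramp, rate, convention)
    ann[[length(ann) + 1]] <- tibble::tibble(
      onset_s = (s0 + n_mask + n_gap) / rate, duration_s = probe_dur,
      label = "probe", freq_hz = probe_freq, level_db = probe_levels[i])
  }
  sound_stimulus(out, rate = rate, annotations = dplyr::bind_rows(ann))
}

#' Synthesize a context-enhancement conditioner/test pair
#'
#' Both sounds are equal-amplitude multitone complexes (components from
#' 200 Hz to 16 kHz at 1/10-octave spacing, random phases) with a spectral
#' notch of the given width carved out around `notch_center`. The test sound
#' adds a tone at the notch centre. The conditioner (500 ms) optionally
#' precedes the test (100 ms); both carry 10-ms ramps and are calibrated to
#' `level`.
#'
#' @param notch_center notch centre frequency in Hz
#' @param notch_width notch width in octaves (0 = no notch)
#' @param conditioner_dur,test_dur segment durations in s
#' @param level calibration level in dB SPL
#' @param with_conditioner include the conditioner before the test?
#' @param seed RNG seed for component phases
#' @param ramp ramp duration in s
#' @param rate sampling rate
#' @return a `sound_stimulus` annotated with the conditioner/test events
#' @export
synth_context_enhancement <- function(notch_center, notch_width = 1,
                                      conditioner_dur = 0.5, test_dur = 0.1,
                                      level = 60, with_conditioner = TRUE,
                                      seed = 1L, ramp = 0.01,
                                      rate = audio_rate()) {
  comp <- octave_grid(200, 16000, 0.1)
  if (notch_center < min(comp) || notch_center > max(comp)) {
    stop("notch centre lies outside the component band", call. = FALSE)
  }
  keep <- abs(log2(comp / notch_center)) >= notch_width / 2 - 1e-9
  if (notch_width == 0) keep <- rep(TRUE, length(comp))
  with_seed(derive_seed(seed, "context"), {
    phases <- stats::runif(length(comp) + 1, 0, 2 * pi)
  })
  complex_tone <- function(freqs, phs, dur) {
    n <- round(dur * rate)
    tt <- (seq_len(n) - 1) / rate
    out <- numeric(n)
    for (i in seq_along(freqs)) out <- out + sin(2 * pi * freqs[i] * tt + phs[i])
    out * cosine_ramp_envelope(n, ramp, rate)
  }
  cond <- complex_tone(comp[keep], phases[which(keep)], conditioner_dur)
  test <- complex_tone(c(comp[keep], notch_center),
                       c(phases[which(keep)], phases[length(phases)]), test_dur)
  cond <- calibrate_level(cond, level, rate = rate)$samples
  test <- calibrate_level(test, level, rate = rate)$samples
  if (with_conditioner) {
    out <- c(cond, test)
    ann <- tibble::tibble(
      onset_s = c(0, length(cond) / rate),
      duration_s = c(conditioner_dur, test_dur),
      label = c("conditioner", "test"),
      freq_hz = notch_center, level_db = level)
  } else {
    out <- test
    ann <- tibble::tibble(onset_s = 0, duration_s = test_dur, label = "test",
                          freq_hz = notch_center, level_db = level)
  }
  sound_stimulus(out, rate = rate, level_db_spl = level, annotations = ann)
}

#' Process a speech (or music) stimulus
#'
#' Applies, in order: a speed increase by plain resampling (no pitch
#' correction), linear multichannel amplification with per-channel gains
#' interpolated on a log-frequency axis, and a high-pass cut. With all
#' arguments at their defaults the input is returned unchanged.
#'
#' @param x a `sound_stimulus`
#' @param speed_factor 1, 2 or 3
#' @param multiband_gains `NULL`, or a two-column matrix / data frame of
#'   (centre frequency Hz, gain dB) pairs, e.g. the standard hearing-aid-like
#'   table `cbind(c(500, 1000, 2000, 4000, 8000), c(3, 10, 17, 22, 25))`
#' @param highpass_hz high-pass cut-off in Hz, or `NULL`
#' @return a processed `sound_stimulus`
#' @export
process_speech <- function(x, speed_factor = 1, multiband_gains = NULL,
                           highpass_hz = NULL) {
  stopifnot(inherits(x, "sound_stimulus"))
  if (!speed_factor %in% c(1, 2, 3)) {
    stop("unsupported speed factor: must be 1, 2 or 3", call. = FALSE)
  }
  s <- x$samples
  if (speed_factor > 1) s <- as.numeric(signal::resample(s, 1, speed_factor))
  if (!is.null(multiband_gains) || !is.null(highpass_hz)) {
    n <- length(s)
    X <- stats::fft(s)
    f <- seq(0, n - 1) * x$rate / n
    f <- pmin(f, x$rate - f)
    G <- rep(1, n)
    if (!is.null(multiband_gains)) {
      mg <- as.matrix(multiband_gains)
      gdb <- stats::approx(log2(mg[, 1]), mg[, 2], xout = log2(pmax(f, 1e-6)),
                           rule = 2)$y
      G <- G * 10^(gdb / 20)
    }
    if (!is.null(highpass_hz)) G[f < highpass_hz] <- 0
    s <- Re(stats::fft(X * G, inverse = TRUE)) / n
  }
  identical_proc <- speed_factor == 1 && is.null(multiband_gains) && is.null(highpass_hz)
  sound_stimulus(s, rate = x$rate,
                 level_db_spl = if (identical_proc) x$level_db_spl else NA_real_,
                 annotations = if (identical_proc) x$annotations else empty_annotations())
}

#' Mix speech and noise at a target SNR
#'
#' The noise is trimmed to the speech length and rescaled so that
#' speech-RMS / noise-RMS equals `10^(snr/20)`; the speech level is preserved.
#'
#' @param speech,noise `sound_stimulus` objects at the same rate
#' @param snr signal-to-noise ratio in dB
#' @return the mixture as a `sound_stimulus` (level metadata from the speech)
#' @export
mix_at_snr <- function(speech, noise, snr) {
  stopifnot(inherits(speech, "sound_stimulus"), inherits(noise, "sound_stimulus"))
  if (speech$rate != noise$rate) stop("rates differ", call. = FALSE)
  if (length(noise$samples) < length(speech$samples)) {
    stop("noise is shorter than the speech", call. = FALSE)
  }
  nz <- noise$samples[seq_along(speech$samples)]
  if (rms(nz) == 0) stop("silent noise cannot be mixed", call. = FALSE)
  nz <- nz * (rms(speech$samples) / rms(nz)) * 10^(-snr / 20)
  sound_stimulus(speech$samples + nz, rate = speech$rate,
                 level_db_spl = speech$level_db_spl,
                 annotations = speech$annotations)
}

#' Intensity addition for extreme centre frequencies
#'
#' Neurophysiological batteries raise the presentation level for very low and
#' very high centre frequencies to stay roughly 30 dB above unit thresholds.
#' The additive table (15, 0, 0, 0, 20, 20) dB anchored at 500, 1000, 2000,
#' 4000, 8000 and 16000 Hz is interpolated linearly on a log2-frequency axis
#' and extrapolated flat beyond the anchors.
#'
#' @param freq_hz centre frequency in Hz (vectorized)
#' @return intensity addition in dB
#' @export
intensity_offset <- function(freq_hz) {
  anchors <- c(500, 1000, 2000, 4000, 8000, 16000)
  add <- c(15, 0, 0, 0, 20, 20)
  stats::approx(log2(anchors), add, xout = log2(freq_hz), rule = 2)$y
}
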