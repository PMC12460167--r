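# Stimulus synthesis: calibration, grid arithmetic, battery structure,
# determinism.

test_that("level calibration follows the RMS convention exactly", {
  fs <- audio_rate()
  x <- sin(2 * pi * 1000 * (0:4999) / fs)
  cal <- calibrate_level(x, 94)
  expect_equal(sqrt(mean(cal$samples^2)), 0.04, tolerance = 1e-12)
  expect_equal(sound_level(cal), 94, tolerance = 1e-9)

  # -20 dB from the reference is exactly a factor 10 in RMS
  cal2 <- calibrate_level(x, 74)
  expect_equal(sqrt(mean(cal2$samples^2)), 0.004, tolerance = 1e-12)

  # querying the level of a waveform with RMS 0.08
  y <- x * 0.08 / sqrt(mean(x^2))
  expect_equal(sound_level(y), 94 + 20 * log10(2), tolerance = 1e-9)

  expect_error(calibrate_level(numeric(100), 70), "zero RMS")
  expect_error(sound_level(numeric(10)), "all-zero")
})

test_that("octave grids reproduce the standard battery counts", {
  expect_length(octave_grid(256, 16384, 0.2), 31)   # FRA frequencies
  cfg_grid <- octave_grid(294, 16384, 0.2)          # CF grid, printed extreme appended
  expect_length(cfg_grid, 31)
  expect_equal(cfg_grid[31], 16384)
  expect_length(octave_grid(500, 11313.71, 0.5), 10)  # forward-masking probes
  expect_length(octave_grid(500, 8000, 0.5), 9)       # AM centre frequencies
  expect_length(octave_grid(2, 512, 1), 9)            # AM modulation frequencies
  expect_length(octave_grid(200, 16000, 0.1), 64)     # context components
  expect_length(seq(4, 103, by = 9), 12)              # FRA levels
  expect_length(seq(4, 85, by = 9), 10)               # CF levels
  expect_length(seq(5, 75, by = 5), 15)               # masking probe levels
  expect_length(seq(0, 2, by = 0.5), 5)               # notch widths
})

test_that("tone batteries have exact envelopes, annotations and level targets", {
  fs <- audio_rate()
  grid <- stimulus_grid(c(1000, 2000), c(60, 70), duration = 0.05,
                        ramp = 0.01, gap = 0.02, repeats = 2, order_seed = 3)
  stim <- synth_tone_battery(grid)
  expect_equal(nrow(stim$annotations), 2 * 2 * 2)
  # envelope is 1.0 over the central 30 ms of a 50-ms tone with 10-ms ramps
  a <- stim$annotations[2, ]
  i0 <- round(a$onset_s * fs)
  tone <- stim$samples[i0 + seq_len(round(0.05 * fs))]
  nr <- round(0.01 * fs)
  mid <- tone[(nr + 1):(length(tone) - nr)]
  amp_expected <- sqrt(2) * 0.04 * 10^((a$level_db - 94) / 20)
  expect_equal(max(abs(mid)), amp_expected, tolerance = 1e-3)
  # annotated onset lands on the envelope transition (+-1 sample): silence
  # right before it, sound energy right after it
  expect_lt(max(abs(stim$samples[i0 + (-5:0)])), 1e-12)
  expect_gt(max(abs(stim$samples[i0 + 1:40])), 0)
  # tone RMS maps back to the annotated dB SPL within 0.01 dB
  steady <- tone[(nr + 1):(length(tone) - nr)]
  expect_equal(sound_level(steady), a$level_db, tolerance = 0.01)
  expect_error(synth_tone_battery(stimulus_grid(1000, 60, duration = 0.05,
                                                ramp = 0.03)),
               "ramp")
})

test_that("moving ripples are deterministic and respect Nyquist", {
  r1 <- synth_moving_ripple(4700, 10800, duration = 0.2, seed = 9)
  r2 <- synth_moving_ripple(4700, 10800, duration = 0.2, seed = 9)
  expect_identical(r1$samples, r2$samples)
  r3 <- synth_moving_ripple(4700, 10800, duration = 0.2, seed = 10)
  expect_false(identical(r1$samples, r3$samples))
  expect_error(synth_moving_ripple(4700, 13000), "Nyquist")
  # depth 0: constant envelope, so the output is the plain carrier sum
  r0 <- synth_moving_ripple(1000, 2000, carrier_step = 0.5, depth = 0,
                            duration = 0.1, seed = 2)
  carriers <- octave_grid(1000, 2000, 0.5)
  env <- sqrt(stats::filter(r0$samples^2, rep(1 / 200, 200), sides = 2))
  env <- env[!is.na(env)]
  expect_lt(stats::sd(env) / mean(env), 0.1)
})

test_that("HPR sequences realize the draw specification exactly", {
  h <- synth_hpr_sequence(21, 96, 1, hpr_center = 39, hpr_range = 12,
                          hpr_draws = 20, other_draws = 1, burst_dur = 0.05,
                          seed = 3)
  expect_equal(nrow(h$annotations), 323)  # 13*20 + 63
  expect_equal(length(h$samples) / h$rate, 16.15, tolerance = 0.005)
  tab <- table(h$annotations$level_db)
  in_hpr <- as.numeric(names(tab)) >= 33 & as.numeric(names(tab)) <= 45
  expect_true(all(tab[in_hpr] == 20))
  expect_true(all(tab[!in_hpr] == 1))
  # per-burst levels calibrate correctly
  fs <- h$rate
  a <- h$annotations[5, ]
  burst <- h$samples[round(a$onset_s * fs) + seq_len(round(0.05 * fs))]
  expect_equal(sound_level(burst), a$level_db, tolerance = 0.01)
  # uniform baseline: 21-96 dB at 2-dB steps is 38 distinct levels
  u <- synth_hpr_sequence(21, 96, 2, hpr_center = NULL, other_draws = 1,
                          burst_dur = 0.01, seed = 1)
  expect_equal(length(unique(u$annotations$level_db)), 38)
  # equal draws = every level equally probable
  e <- synth_hpr_sequence(30, 50, 5, hpr_center = 40, hpr_range = 10,
                          hpr_draws = 2, other_draws = 2, burst_dur = 0.01)
  expect_true(all(table(e$annotations$level_db) == 2))
  expect_error(synth_hpr_sequence(21, 96, 1, hpr_center = 10), "invalid HPR")
})

test_that("AM noise stays in band and envelopes behave", {
  fs <- audio_rate()
  s <- synth_am_noise(2000, mod_freq = 16, duration = 0.5, level = 60, seed = 4)
  X <- abs(stats::fft(s$samples))^2
  f <- (seq_along(X) - 1) * fs / length(X)
  f <- pmin(f, fs - f)
  in_band <- f >= 2000 / sqrt(2) * 0.9 & f <= 2000 * sqrt(2) * 1.1
  expect_gt(sum(X[in_band]) / sum(X), 0.99)
  # depth 0 equals unmodulated noise
  s0 <- synth_am_noise(2000, mod_freq = 16, depth = 0, duration = 0.1, seed = 4)
  su <- synth_am_noise(2000, mod_freq = 0, duration = 0.1, seed = 4)
  expect_identical(s0$samples, su$samples)
  expect_error(synth_am_noise(2000, mod_freq = 20000), "Nyquist")
  expect_error(synth_am_noise(2000, mod_freq = 16, envelope = "square"),
               "unknown envelope")
  # raised-sine-32 concentrates energy near the envelope peaks
  s32 <- synth_am_noise(2000, mod_freq = 8, envelope = "raised-sine-32",
                        duration = 0.5, seed = 4)
  expect_true(all(is.finite(s32$samples)))
})

test_that("forward masking sequences carry masker/probe structure", {
  m <- synth_forward_masking(2000, probe_levels = c(40, 60),
                             masker_level = 70)
  expect_equal(sum(m$annotations$label == "masker"), 2)
  expect_equal(sum(m$annotations$label == "probe"), 2)
  pr <- m$annotations[m$annotations$label == "probe", ]
  mk <- m$annotations[m$annotations$label == "masker", ]
  # probe onset = masker offset + 10 ms gap (on the sample grid)
  expect_equal(pr$onset_s[1], mk$onset_s[1] + 0.2 + 0.01,
               tolerance = 2 / audio_rate())
  un <- synth_forward_masking(2000, probe_levels = c(40, 60))
  expect_true(all(un$annotations$label == "probe"))
})

test_that("context-enhancement complexes carve the notch and annotate", {
  ce <- synth_context_enhancement(2000, notch_width = 1, seed = 5)
  expect_equal(ce$annotations$label, c("conditioner", "test"))
  expect_equal(ce$annotations$duration_s, c(0.5, 0.1))
  t_only <- synth_context_enhancement(2000, notch_width = 1, seed = 5,
                                      with_conditioner = FALSE)
  expect_equal(nrow(t_only$annotations), 1)
  expect_error(synth_context_enhancement(50), "outside the component band")
  # notch removes spectral energy around the centre in the conditioner
  fs <- ce$rate
  cond <- ce$samples[seq_len(round(0.5 * fs))]
  X <- abs(stats::fft(cond))^2
  f <- (seq_along(X) - 1) * fs / length(X); f <- pmin(f, fs - f)
  notch_pow <- mean(X[f > 2000 * 2^-0.3 & f < 2000 * 2^0.3])
  band_pow <- mean(X[f > 2000 * 2^0.7 & f < 2000 * 2^1.3])
  expect_lt(notch_pow, band_pow / 100)
})

test_that("speech processing applies resampling, channel gains and high-pass", {
  fs <- audio_rate()
  tone <- calibrate_level(sin(2 * pi * 2000 * (0:24413) / fs), 70)
  expect_identical(process_speech(tone)$samples, tone$samples)
  sp2 <- process_speech(tone, speed_factor = 2)
  expect_equal(length(sp2$samples), length(tone$samples) / 2)
  expect_error(process_speech(tone, speed_factor = 4), "unsupported speed")
  gains <- cbind(c(500, 1000, 2000, 4000, 8000), c(3, 10, 17, 22, 25))
  amp <- process_speech(tone, multiband_gains = gains)
  expect_equal(sound_level(amp$samples) - 70, 17, tolerance = 0.01)
  hp <- process_speech(tone, highpass_hz = 6000)
  expect_lt(sqrt(mean(hp$samples^2)), 1e-3 * sqrt(mean(tone$samples^2)))
})

test_that("SNR mixing preserves speech level and power adds", {
  set.seed(20)
  sp <- sound_stimulus(stats::rnorm(2e5)); nz <- sound_stimulus(stats::rnorm(2e5))
  sp$samples <- sp$samples / sqrt(mean(sp$samples^2))
  nz$samples <- nz$samples / sqrt(mean(nz$samples^2))
  m0 <- mix_at_snr(sp, nz, 0)
  expect_equal(sqrt(mean(m0$samples^2)), sqrt(2), tolerance = 0.01)
  m20 <- mix_at_snr(sp, nz, 20)
  noise_part <- m20$samples - sp$samples
  expect_equal(sqrt(mean(noise_part^2)), 0.1, tolerance = 1e-6)
  expect_error(mix_at_snr(sp, sound_stimulus(numeric(2e5)), 0), "silent")
  expect_error(mix_at_snr(sp, sound_stimulus(stats::rnorm(10)), 0), "shorter")
})

test_that("intensity offsets interpolate the standard additive table", {
  expect_equal(intensity_offset(c(500, 1000, 2000, 4000, 8000)),
               c(15, 0, 0, 0, 20))
  expect_equal(intensity_offset(707.1068), 7.5, tolerance = 1e-3)
  expect_equal(intensity_offset(300), 15)   # flat extrapolation below
  expect_equal(intensity_offset(20000), 20) # and above
})

test_that("stimuli round-trip through WAV + sidecar", {
  s <- synth_am_noise(1000, mod_freq = 8, duration = 0.05, level = 60, seed = 2)
  path <- tempfile(fileext = ".wav")
  write_stimulus(s, path)
  r <- read_stimulus(path)
  expect_equal(r$samples, s$samples, tolerance = 1e-6)
  expect_equal(r$rate, s$rate)
  expect_equal(r$level_db_spl, 60)
})
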