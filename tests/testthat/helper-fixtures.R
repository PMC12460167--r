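# Shared fixtures: a desk-scale model configuration and cached simulator
# outputs so expensive objects are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Small configuration used throughout: 5 stride-2 layers (so the canonical
# 32x decimation holds) with narrow widths and short kernels.
small_cfg <- function(n_classes = 5, time_module = "none", context = 512,
                      frame = 2048) {
  model_config(n_front = 8, front_kernel = 16, n_enc = 16, enc_kernel = 8,
               n_bneck = 8, bneck_kernel = 8, context = context, frame = frame,
               n_classes = n_classes, time_module = time_module)
}

micro_cfg <- function(n_classes = 5, time_module = "none") {
  model_config(n_front = 4, front_kernel = 8, n_enc = 5, enc_kernel = 6,
               n_bneck = 4, bneck_kernel = 6, context = 32, frame = 64,
               n_classes = n_classes, time_module = time_module,
               time_hidden = 6)
}

# A quiet, memoryless simulator world (no gain jitter, no adaptation) where
# counts are exactly binomial(4, rate/4) given the sound.
memoryless_population <- function(M, seed = 5, ...) {
  make_population(M, seed = seed,
                  config = utils::modifyList(
                    list(jitter_sd = 0, adapt_strength = 0), list(...)))
}

# Uniform noise-burst level sweep, the workhorse training stimulus.
level_sweep_stimulus <- function(seed, step = 3) {
  synth_hpr_sequence(21, 96, step, hpr_center = NULL, other_draws = 2,
                     burst_dur = 0.05, seed = seed)
}

training_frames <- function(cfg, pop, n_sessions = 3, seed0 = 1) {
  sessions <- lapply(seq_len(n_sessions), function(i) {
    stim <- level_sweep_stimulus(seed0 + i)
    resp <- simulate_counts(pop, stim, rec_time = 0, trials = 1,
                            seed = 10 + i)[[1]]
    recording_session(stim, resp, id = paste0("sweep", i))
  })
  frame_dataset(sessions, cfg, seed = 4)
}
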