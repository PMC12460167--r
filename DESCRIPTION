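Package: spikecoder
Title: Encoder-Decoder Modelling of Sound-Evoked Spike Counts in the Auditory Midbrain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling multi-unit spike-count responses of the
    inferior colliculus to arbitrary sound. Provides calibrated synthesis of
    the standard neurophysiological stimulus batteries (tone grids, dynamic
    moving ripples, high-probability-region noise sequences,
    amplitude-modulated noise, forward-masking and context-enhancement
    complexes), extraction of binned multi-unit activity from raw
    extracellular traces, a trainable convolutional encoder-decoder that maps
    sound waveforms (plus an optional recording-time input) to per-unit count
    distributions under either a Poisson or a bounded categorical likelihood,
    a linear-nonlinear baseline on mel spectrograms, noise-corrected
    evaluation metrics (RMSE, log-likelihood, explainable correlation and
    variance, coherence, Fano factors, modulation transfer functions,
    non-stationarity index), and a controllable synthetic midbrain population
    simulator for end-to-end testing without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
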