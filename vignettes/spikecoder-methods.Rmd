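---
title: "Modelling auditory-midbrain spike counts with spikecoder: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling auditory-midbrain spike counts with spikecoder: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikecoder)
```

## The problem

Neurons in the inferior colliculus (IC), the principal midbrain hub of the
auditory pathway, transform sound into trains of action potentials. A
practical way to study this code at scale is multi-unit activity (MUA):
threshold crossings of the high-pass-filtered extracellular voltage on each
electrode channel, binned at high temporal resolution. `spikecoder` provides
a complete desk-scale workbench for modelling this transformation: it
synthesizes the standard calibrated stimulus batteries, converts raw traces
to binned counts, fits a convolutional encoder--decoder that maps the sound
waveform (and, optionally, the recording time) to a per-unit, per-bin
probability distribution over spike counts, and evaluates predictions with
noise-corrected metrics. A controllable synthetic IC population closes the
loop so that every stage can be validated against known ground truth without
animal data.

All sound is processed at 24,414.0625 Hz, and one spike-count bin spans
exactly 32 audio samples (762.9395 Hz, about 1.31 ms), so count bins stay
sample-locked to the waveform throughout.

## Sound level as a pure RMS convention

Sound level carries no frequency weighting here: a waveform with RMS
amplitude 0.04 is *defined* to be at 94 dB SPL, and level scales as
$L(x) = 94 + 20\log_{10}(\mathrm{RMS}(x)/0.04)$. `calibrate_level()`
rescales a waveform to any target level under this convention, and every
generator that takes a level produces output that round-trips through
`sound_level()` to within 0.01 dB. This convention also fixes the input
scaling of the model: calibrated waveforms arrive with RMS near 0.04 at
conversational levels, which keeps the network inputs numerically
well-scaled without a separate normalization stage.

## Stimulus batteries

The generators cover the standard IC characterization suite. All of them are
pure functions of their arguments and a seed; identical calls produce
bit-identical waveforms, and every event (tone, burst, probe) is annotated
with its onset, duration, frequency and level so analysis windows can be
placed downstream without bookkeeping.

* **Tone grids** (`synth_tone_battery()`): ramped pure tones over a
  frequency × level grid in seeded random order, for frequency-response
  areas and characteristic-frequency (CF) estimation. Octave-spaced grids
  follow a single endpoint rule (`octave_grid()`): lattice points
  $f_{lo}2^{ks}$ up to $f_{hi}$, with a printed endpoint appended when it
  misses the lattice by less than 0.5% (printed values within 10 ppm of a
  lattice point are treated as that point, merely rounded). This reproduces
  the battery extremes printed in the experimental literature, e.g. 31 frequencies for both the
  256--16,384 Hz and the 294--16,384 Hz grids at 1/5-octave spacing.
* **Dynamic moving ripples** (`synth_moving_ripple()`): sinusoid series at
  0.02-octave spacing with random phases, jointly modulated so the
  instantaneous temporal rate spans 0--10 Hz, the spectral density spans
  0--4 cycles/octave, and the depth is 50 dB. The modulation-rate
  trajectories are piecewise-linear interpolations of uniform draws every
  0.5 s — descriptions of these stimuli in the literature state ranges only, so the trajectory
  distribution (uniform, resampled per stimulus) is a design choice of this
  package.
* **High-probability-region (HPR) sequences** (`synth_hpr_sequence()`):
  concatenated 50-ms noise bursts whose integer-dB levels are drawn so that
  each of the 13 levels inside a 12-dB HPR appears 20 times and every other
  level once — 323 bursts, 16.15 s, no inter-burst silence. A 12-dB "range"
  is read as 13 integer levels inclusive; this is forced by the printed
  sequence duration (323 × 50 ms).
* **AM noise, forward masking, context enhancement**: one-octave noise bands
  with sinusoidal or raised-sine-N envelopes; masker--gap--probe tone
  sequences with the 10-ms pause and the 7.9--20-ms probe analysis window;
  notched multitone complexes with a test tone at the notch centre. The
  "sinusoid raised to the power N" envelope is implemented as
  $(1-d) + d\,((1-\cos 2\pi f t)/2)^N$, which reduces to full-depth
  sinusoidal AM at $N = 1$, $d = 1$.
* **Speech-like processing** (`process_speech()`, `mix_at_snr()`): plain
  resampling for speed changes (no pitch correction), linear multiband
  gains interpolated on a log-frequency axis (so a 2-kHz tone through the
  standard 3/10/17/22/25-dB table gains exactly 17 dB), brick-wall
  high-pass, and SNR mixing that preserves the speech level. Noise is
  trimmed, not looped, to the speech length. The intensity-addition table
  for extreme centre frequencies is anchored at 500--16,000 Hz with values
  (15, 0, 0, 0, 20, 20) dB and interpolated linearly in log-frequency; the
  source table in the experimental literature prints six values against five
  frequencies, and anchoring
  the sixth value one octave above 8 kHz (flat beyond) is this package's
  resolution of that ambiguity.

Cosine ramps are raised-cosine half-windows applied on top of the steady
amplitude, with the ramp time counted inside the stated duration. Noise is
Gaussian, band-limited by brick-wall FFT filtering, and regenerated from the
seed per burst.

## From raw traces to MUA

`extract_mua()` implements the standard chain: zero-phase (forward-backward)
4th-order Butterworth band-pass at 700--5,000 Hz, a robust noise-SD estimate
as median absolute deviation / 0.6745, counting of positive-going crossings
of 3.5 SD per 1.31-ms bin, and clipping at 4 counts/bin (the pre-clip
fraction above 4 is reported per unit). Zero-phase filtering is chosen so
the filter adds no latency bias to the binning; descriptions of the procedure name only the cut-offs.

`estimate_cf()` finds the characteristic frequency as the tone frequency
with a statistically significant response at the lowest intensity.
Significance uses the exact Poisson upper tail at $\alpha = 10^{-4}$ with
rate $\max(\text{silence rate}, 1/8)$ scaled to the window summed over all
repeats — summation over repeats is implied by the rate floor of 1/8 with 8
presentations. At $\mu = 1$ the significance threshold is 7 counts. Ties at
the lowest significant level go to the larger count, then to the lower
frequency. The silence rate is estimated from bins not covered by any tone
presentation; batteries must therefore leave genuine inter-tone silence
(with 75-ms gaps the estimate is well-defined; with very short gaps the
1/8 floor takes over and the test becomes anticonservative).

`qc_units()` computes the signal correlation (per-unit correlation of binned
counts across two repeats of the same broadband stimulus) and flags units at
or above 0.2 — the threshold is inclusive, and zero-variance units are
excluded as undefined.

## The encoder--decoder

The model maps a frame of `frame` audio samples plus `context` samples of
left context to count distributions for `frame/32` bins:

1. a bank of learnable band-pass filters (sinc-type parametrization: each
   filter is the difference of two windowed sinc low-passes, with the two
   cut-offs as the learnable parameters), followed by the symmetric
   logarithm $y = \mathrm{sgn}(x)\log(|x|+1)$;
2. five causal 1-D convolutions with stride 2 and parametric rectifiers
   (one learnable slope per channel, initialized at 0.25) — total
   decimation $2^5 = 32$;
3. a stride-1 bottleneck convolution (64 channels at full scale) and a crop
   of the left `context/32` bins, which removes convolutional edge effects;
4. per-animal linear decoders (1×1 convolution, no bias) to units × $N_c$
   outputs: $N_c = 1$ with a softplus head (Poisson rate) or $N_c = 5$ with
   a softmax head (categorical distribution over counts 0--4).

The Poisson loss is $\sum_{m,t} (\lambda - R\log\lambda)$; the categorical
loss is the one-hot cross-entropy of the observed count (clipped at 4). A
variant sometimes written for this loss multiplies class log-probabilities
by the observed count itself, which degenerates at $R = 0$; the one-hot
indicator is the standard cross-entropy over possible counts and is what
this package implements.

Recording time enters in one of two ways. At the audio rate, time (seconds,
scaled by 1/36,000 at the model boundary) passes through a bias-free 1×1
map and symmetric log, and is concatenated with the filterbank output, which
doubles the channel count into the first encoder layer. At the bottleneck
rate, a per-animal 1×1 map with bias and rectifier (or, in the complex
variant, a cascade of four 1×1 layers — three hidden layers at the
configured width and a final layer matching the bottleneck width, since a
128-wide final layer cannot multiply a 64-channel bottleneck
elementwise) produces a gate that multiplies the bottleneck. A fixed time
input makes the model exactly stationary, which is how time-invariant
"snapshots" of a time-variant model are taken.

Front-end cut-offs are initialized mel-spaced over 50 Hz--12 kHz and are
clamped to valid band edges (positive, ordered, below Nyquist) during
training; gradients through a clamped parameter are zeroed at the boundary.
Causal convolutions are implemented as left zero-padding of kernel−1
samples.

The network, its exact backpropagation, and the Adam optimizer are written
in R against BLAS matrix primitives (im2col convolutions with memoized
gather indices). Backpropagation is verified against central-difference
numerical gradients for every parameter group and every architecture
variant in the test suite.

### The LNP baseline

`mel_spectrogram()` computes short-time power spectra (window 512, hop 32 —
left-aligned windows with reflect padding so the frame count equals
samples/32 and the frame rate matches the count bins), maps them to 96 mel
bands over 50 Hz--12 kHz, converts to dB with a +7 dB offset and squashes
through a sigmoid. `lnp_fit()`/`lnp_forward()` implement per-unit Poisson
regression with causal spectro-temporal kernels, an exponential output
nonlinearity, and an L2 kernel penalty of $10^{-5}$.

## Training protocol

`train()` implements the full reference protocol: Adam with batches of 50
frames and a starting learning rate of 4×10⁻⁴; the learning rate is halved
when the validation loss fails to improve for two consecutive epochs;
training stops after four such epochs; 10% of frames form the validation
split (seeded; splitting by whole sounds is available as an option). The
weights restored at the end are those of the best validation epoch — the
schedule specification covers halving and stopping only, and restoring
the best checkpoint is the conventional companion of early stopping.
Framing is non-overlapping (the frame and context arithmetic implies no overlap), with the left context taken from the preceding
audio and zero-padded at the session start.

Desk-scale experiments in the tests and the acceptance script use a reduced
configuration — 8 front-end filters (kernel 16), 16 encoder filters (kernel
8), an 8-channel bottleneck, 2,048-sample frames with 512-sample context,
8--16 units, batches of 8 and a learning rate of 4×10⁻³ with at most 25--30
epochs — chosen so that a full train/evaluate cycle takes about a minute
per model while leaving the stride structure (and hence all rate
arithmetic) identical to the full-scale model. The learning rate is scaled
up relative to the full protocol because the scaled-down problems are far
smaller; the schedule rules themselves are unchanged.

## Evaluation metrics

All metrics take units × bins count matrices. Predictions enter RMSE,
correlation explained and coherence as *sampled* responses (seeded draws
from the predicted distribution), while variance explained uses
distribution *expectations* — matching how each quantity is defined.

* RMSE and mean log-likelihood of the observed count.
* **Correlation explained (%)**: $\tfrac{100}{2}\,
  (\rho(R_1,\hat R_1)+\rho(R_2,\hat R_2))/\rho(R_1,R_2)$ on flattened
  responses; per-unit mode computes over time only. Values above 100% are
  possible in non-stationary recordings; a non-positive trial-pair
  correlation makes the quantity undefined (`NA`, with a warning).
* **Variance explained (%)**: the noise-corrected error variance relative
  to explainable variance, with $\sigma^2_{noise} = \tfrac12
  \mathrm{Var}[R_1-R_2]$. Population variances (divide by $n$) are used
  throughout so that degenerate fixtures return exactly 100% and 0%.
* **Coherence**: unit-averaged magnitude-squared coherence from Hann-
  windowed non-overlapping segments of 763 bins; the prediction-vs-recording
  version averages the two trial pairings. Independent noise gives a
  baseline of 1/(number of segments).
* **Fano factors**: across-trial population variance over mean per bin,
  averaged over window bins with non-zero mean.
* **Synchrony MTFs**: $|X(f_{mod})|^2/|X(0)|^2$ of the trial-averaged
  response over a 763-bin window starting 7.9 ms after onset.
* **Non-stationarity index**: absolute difference between the mean
  covariance of flattened responses on successive trials and on trials
  hours apart.
* **Bottleneck PCA**: principal components over time of the
  silence-referenced bottleneck (silence mean subtracted, divided by −500
  to match the scale and sign of MUA).

A single window rule converts analysis windows to bins everywhere: $[a, b)$
seconds maps to bins $\lceil a r\rceil \dots \lceil b r\rceil - 1$, so the
7.9-ms window start excludes exactly the first 6 bins. Undefined cells
(zero variance, zero d.c.) are masked, excluded from averages, and counted.
Bootstrap CIs resample across units (1,000 resamples at full scale; the
desk-scale default in `evaluate_model()` is 200).

## The synthetic IC population

`make_population()` draws per-unit parameters reproducibly: log-uniform CFs
over 300 Hz--12 kHz (sorted, i.e. tonotopic order), Gaussian-on-log-frequency
tuning widths of 0.3--0.8 octaves, thresholds of 15--55 dB SPL, dynamic
ranges of 20--40 dB, maximum rates of 1.5--3.5 counts/bin, a spontaneous
floor of 0.02 counts/bin, divisive gain control with a 100-ms memory, 10%
log-normal per-trial gain jitter, and an optional session-long gain-drift
profile (linear, exponential or sinusoidal over a 12-h session). These
defaults are intended as "typical IC-like" orders of magnitude; every one
of them is overridable through the config.

`simulate_counts()` computes, per bin: the band level at each unit's CF from
a *causal* short-time spectrum (windows end at the bin's last sample, so a
bin's drive never depends on future audio — a requirement for the simulator
to be learnable by a causal model); a gain-control stage that divides the
band amplitude by an exponential memory of itself (subtractive on the dB
axis), which both shifts rate--intensity functions toward the prevailing
level under HPR stimulation and produces forward masking; a sigmoidal
rate--intensity function; multiplicative drift evaluated at the recording
time; and finally counts drawn as binomial(4, rate/4) — bounded at the
4-count ceiling and analytically underdispersed with Fano $= 1 - r/4$
(0.75 at one count/bin). A `poisson_mix` parameter blends in clipped
Poisson draws when more dispersion is wanted. An earlier divisive stage
acting on the *rate* was replaced by the amplitude-domain gain control:
pure division of the output rate rescales a rate--intensity curve without
moving its midpoint, so it cannot reproduce dynamic-range adaptation.

`simulate_raw_trace()` renders counts from a small unit group as biphasic
spike waveforms on Gaussian background noise at 20 kHz, with the
ground-truth per-bin event counts returned, so threshold-crossing
extraction can be validated end to end.

### What the simulator does and does not emulate

It reproduces the response *statistics* the modelling framework targets —
tonotopy, sigmoidal rate--intensity functions, adaptation phenomena,
underdispersed bounded counts, slow drift, controllable reliability. It is
not a biophysical cochlea or IC model: there are no realistic
spectro-temporal receptive fields beyond Gaussian frequency weighting, no
synchrony to fine structure, and no across-unit noise correlations beyond
what the shared stimulus induces. Tests passing on the simulator therefore
demonstrate that the pipeline recovers what it was pointed at under
controlled conditions, not that the architecture captures real IC coding.

## Desk-scale experiment design

Three end-to-end claims are exercised at desk scale (the scaled-down
configuration above), with conditions chosen as follows:

* **Likelihood heads and dispersion.** Data are generated in the simulator's
  memoryless regime (gain jitter and adaptation off), so that the
  conditional count law given the sound is exactly binomial — the cleanest
  realization of "underdispersed data" for a likelihood comparison. Jitter
  and long-memory adaptation would add components that no sound-driven
  model can resolve, inflating the predictive entropy of both heads for
  reasons unrelated to the count law. Matched categorical and Poisson
  models are trained on noise-burst level sweeps; per-unit Fano factors of
  sampled responses are compared with the simulator's ground truth, and the
  categorical model's absolute error is smaller on (nearly) every unit —
  the Poisson head cannot represent sub-Poisson dispersion, its sampled
  Fano sitting near 1 regardless of the data.
* **Time conditioning.** Linear gain drift at magnitudes 0.15/0.45/0.75
  over a 10-h session; training sounds presented at four session times;
  held-out sounds evaluated late in the session (9 h and 9.3 h), with RMSE
  averaged over two reference trials and three sampled predictions. The
  time-variant model (bottleneck-rate gate) achieves lower late-session
  RMSE than the matched time-invariant model, and the benefit grows with
  drift magnitude.
* **Transfer.** A single-branch model is trained on "animal A", its encoder
  frozen, and a fresh decoder branch fitted on "animal B"; the resulting
  held-out loss is compared with a fully trained single-branch model on B.
  The frozen-encoder transfer lands within 5% of the full model, and the
  encoder weights are verified byte-identical before and after.

## Numerical and degenerate-input choices

* Exact Poisson tails (`ppois`), never a normal approximation, for the CF
  significance rule.
* Losses guard logarithms at $10^{-12}$; a zero rate (or zero class mass)
  at an observed count is reported as an infinite loss with a warning
  rather than silently clipped.
* Poisson sampling clips at 4 counts/bin, matching the count ceiling used
  everywhere.
* All randomness — initialization, batching, splits, sampling, synthesis —
  flows through a single run-level seed via an internal stream-derivation
  helper, so the full pipeline is bit-reproducible on one machine.
* Degenerate metrics (zero trial-pair correlation, zero explainable
  variance, zero d.c.) return `NA` with a warning and are excluded from
  unit averages with a logged count, never folded in as zeros.

## Known limitations

* Training in R is practical at desk scale (seconds per epoch for the
  reduced configuration) but not at the scale of 10-h recordings
  and 512-unit decoders; the package's claims are therefore about
  correctness and qualitative behaviour, not headline accuracy numbers.
* The WAV/TSV/JSON containers favour transparency over compactness; very
  long recordings are better kept as waveform + seed recipes than as files.
* The simulator's band-level front end shares its STFT machinery with the
  mel spectrogram; its frequency resolution (512 samples, ~21 ms) limits
  how sharply tuned a synthetic unit can be at low CFs.
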