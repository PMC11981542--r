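---
title: "Modelling vocal individuality over propagation distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vocal individuality over propagation distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aukprop)
```

## The question this package addresses

Colonial seabirds such as the little auk (*Alle alle*) broadcast social
calls that are strongly individually specific at the source. Whether that
identity information is still present after the call has crossed tens or
hundreds of metres of Arctic air is a different question: the atmosphere
acts as a distance-dependent low-pass filter, and sound-level decay pushes
the signal toward the receiver's hearing threshold. `aukprop` implements a
desk-scale answer: it filters calibrated recordings exactly as the
atmosphere would (no noise, no wind, no topography) and asks the
statistical machinery of vocal-individuality research whether a classifier
— or an information measure — can still tell the callers apart.

## The propagation model

The level of a frequency component f at distance r from a source
referenced at r0 = 1 m is modelled as

    L(r, f) = L(r0, f) - 20 log10(r / r0) - alpha(f) (r - r0)

the first term being spherical spreading from an omnidirectional point
source, the second the atmospheric absorption of ISO 9613-1, with alpha in
dB/m determined by temperature, pressure and relative humidity through the
molecular relaxation frequencies of oxygen and nitrogen. The package embeds
the ISO closed forms directly (`saturation_vapor_pressure_ratio()`,
`molar_water_concentration()`, `relaxation_frequencies()`,
`absorption_coefficient()`); the test suite pins them against an
independently coded single-file evaluation to 1e-9 dB/m over a grid of
Arctic-summer conditions.

Two numerical choices deserve note. First, the level form above is the
standard outdoor-acoustics resolution of mixing a logarithmic quantity
with the multiplicative factors (1/r)^2 and e^(-a r): both are converted
to dB and added. Second, absorption is applied over (r - r0), not r, so
the gain is exactly zero at the reference distance; the difference is at
most alpha(f) x 1 m, negligible against 60 dB of spreading loss at 1 km,
but it keeps the identity `attenuate(wave, r0) == wave` exact.

Waveform filtering (`attenuate_waveform()`) uses a single whole-signal
real FFT with a per-bin magnitude gain and zero phase change. The gain
varies only with frequency, not time, so a short-time transform would add
overlap-add artifacts without adding physics. Attenuated output is written
as float32 WAV: at 1000 m the signal sits more than 60 dB below the
original and would disappear into 16-bit quantisation.

The modelled distance grid is the truncated log-spaced decade grid
`floor(10^(k/3))`-style sequence 1, 2, 4, 10, 21, 46, 100, 215, 464,
1000 m (`distance_grid()`), and conditions are long-term monthly means for
the four breeding-season months, so one source call becomes 40 modelled
calls.

## Calibration and levels

End-to-end calibration (`calibration_offset()`) maps full-scale sample
units to dB re 20 uPa using a recorded reference tone of known meter
level. Apparent sound pressure levels are measured as the peak sample
level and as RMS over the 95%-energy window — the contiguous segment
between the 2.5% and 97.5% points of cumulative squared-sample energy.
The symmetric-tail convention is a deliberate choice (the criterion alone
does not fix the tails) and makes the measure deterministic and
insensitive to leading/trailing silence. Source levels at 1 m follow the
spherical back-calculation `SL = ASPL - 20 log10(r0 / r_meas)`; for the
conventional 10 cm microphone distance this subtracts exactly 20 dB.
Population level summaries average hierarchically — calls within
individual first, then individuals — so well-sampled birds do not
dominate, and the two call types are compared with a Welch t-test on the
individual means.

## The 15-parameter feature set

`extract_features()` measures, per call: duration (first to last
non-silent 5 ms STFT frame, 60 dB dynamic range); amplitude-modulation
depth and rate from a 100 Hz-low-passed envelope, plus a
modulation-spectrum rate (FFT of spectrogram rows); mean frame RMS;
cepstral peak prominence; lowest dominant frequency band; pitch and its
frame-to-frame modulation depth from autocorrelation restricted to
500-2000 Hz; spectral power quartiles Q25/Q50/Q75; spectral centroid; and
the dB/kHz spectral slope. These re-implement the plain-language
definitions of the protocol's feature table; numeric parity with any
particular analyzer is *not* claimed — what the pipeline relies on, and
what the tests enforce, is self-consistency across the distance grid
(centroid and Q75 fall with distance while pitch stays within 2%, the
mechanism by which fundamental-frequency identity cues survive
attenuation).

Settings worth knowing (all in `analysis_settings()`): 40 ms Gaussian
window (20 periods of a 500 Hz fundamental), 5 ms step, voicing threshold
0.45 on the normalised autocorrelation peak, and a requirement that the
autocorrelation maximum be interior to the lag band — a band-edge maximum
means the true period is outside 500-2000 Hz and the frame is unvoiced
(this is what keeps a 300 Hz tone from aliasing into the band). Frames are
centre-padded so call edges resolve to the step, and the silence criterion
uses the central step-length slice of each frame rather than the whole
window, so duration has no window-length bias. Spectral quantiles and CPP
are defined on voiced frames and fall back to non-silent frames for
unvoiced signals. AM depth is the robust envelope spread
(q98 - q02)/(q98 + q02), which recovers the modulation index of
sinusoidal AM; envelope dropouts shorter than 50 ms (the zeros of full
modulation) do not split a syllable.

## Individuality statistics

The reduction and inference chain mirrors standard practice in vocal
individuality work: Kaiser-Meyer-Olkin adequacy on the cleaned feature
table, PCA on the correlation matrix with Kaiser retention (eigenvalue
> 1), then

* **Nested permuted DFA** (`nested_pdfa()`): linear discriminant
  classification with a control factor (the source file) whose groups move
  as blocks under permutation, correcting for the fact that every source
  call appears once per month. A balanced random 2/3 of each individual's
  control groups trains the discriminant; accuracy is reported on the
  training rows and on the held-out rows, against a permutation-derived
  chance level, with the add-one p estimator (1 + #{perm >= obs}) /
  (1 + n_perm). The permutation seed is a required argument and ships
  with the result. Under a shuffled-label null the test is slightly
  conservative (accuracy ties inflate p), which the acceptance suite
  quantifies: the 5% rejection rate sits near 0.03-0.05.

* **Beecher's Hs** (`beechers_hs()`): per variable, one-way ANOVA across
  individuals gives F, and HS_i = log2 sqrt((F + n - 1)/n) with n the
  (harmonic-mean) observations per individual, floored at zero; under the
  balanced one-way model its expectation is 0.5 log2(1 + s2_b/s2_w),
  which the test suite verifies by simulation to within 0.15 bits.
  `hs_all` sums all variables, `hs_significant` only those with raw
  ANOVA p < 0.05, and round(2^hs) — computed on the unrounded statistic —
  is the theoretical number of distinguishable individuals. The function
  sums whatever variables it is given; the pipeline's per-distance Hs
  stage feeds it the Kaiser-retained components rather than all scores.
  The reason is the independence assumption behind the summation: under
  heavy attenuation, spectral-location features (median frequency, peak,
  dominant band) all collapse onto the surviving fundamental, and with
  all components retained the same F0 cue is counted several times more
  at 1000 m than at 1 m, inflating the long-distance capacity; on the
  retained subset the collapsed copies consolidate into one factor.

* **Supervised embedding + SVM** (`supervised_embed()`,
  `weighted_accuracy()`, `classify_by_distance()`): a 2-D supervised
  embedding per distance, then a class-weighted RBF support-vector
  classifier on a stratified 80:20 split, and OLS of accuracy on
  log10(distance) as the degradation test. The embedding backend shipped
  here is a Fisher discriminant Sammon mapping: supervision enters through
  projection onto all linear discriminant axes, and Sammon's nonlinear
  stress then lays that configuration out in 2-D. The nonlinearity
  matters: truncating to the first two discriminant axes collapses
  between-class structure exactly where the feature space degenerates
  (heavily attenuated calls), while the Sammon layout preserves it — the
  same property for which neighbourhood-graph embeddings are chosen in
  this literature. The `embedding_config()` object retains the
  `n_neighbors`/`min_dist` fields so such a backend (UMAP and kin) can be
  swapped in without touching call sites — those two fields are inert for
  the discriminant-Sammon backend. Note the protocol's
  order of operations embeds *before* splitting, so the embedding has
  seen the test labels; `aukprop` replicates that order deliberately and
  flags it here: per-distance accuracies are internal-consistency
  measures, not generalisation estimates.

Cleaning (`clean_table()`) removes rows with any missing feature and
individuals with fewer than 200 remaining entries (five calls x four
months x ten distances).

## The synthetic-data generator

`make_individuals()` draws per-individual signatures — fundamental
frequency (800-1400 Hz, within-individual SD 3-6%, so individuals overlap
as real callers do), syllable duration,
AM rate (8-28 Hz), spectral tilt (-7 to -2.5 dB/kHz), two formant-like
envelope peaks, and a source level (65-80 dB peak at 10 cm, matching the
published range for nest-recorded calls) — and `synthesize_call()`
realises them as harmonic additive synthesis on a jittered F0 contour:
*classic* calls are 3-5 syllables with 80-200 ms gaps (1-3 s total),
*single* calls one syllable under 0.5 s. Every signature dimension is
re-drawn around its individual mean for every call (frequency jitter, AM
rate +/-12%, tilt SD 0.5 dB/kHz, formant positions +/-4%, level SD
1.5 dB): calls are never carbon copies, so no extracted feature is
individual-deterministic and ANOVA F statistics stay finite — the
degenerate alternative would make information measures arbitrarily large.
`synth_meteo()` supplies plausible High-Arctic monthly means (May -3.8 degC
to July +4.9 degC, RH 82-87%, ~1010 hPa, small seeded jitter); these are
documented defaults, not station ground truth.

What the generator does *not* emulate — and therefore what green tests do
not establish about field data: vocal-tract resonance dynamics, syllable
hand-offs, background noise, wind, reverberation, clipping, or the
near-field recording physics of a microphone 10 cm from a bird in a rock
crevice. The generator's single contract is carrying controllable,
recoverable identity signatures through the full DSP and statistics
chain. `simulate_feature_table()` bypasses the DSP entirely and writes
feature tables with exact variance components, which is what anchors the
Hs-recovery and permutation-calibration tests.

## Problem sizes and reproducibility

The deliberately desk-scale default checks run: the headline end-to-end
property (6 individuals x 8 single-type calls x 4 months x 10 distances,
200 pDFA permutations) in about 5 minutes on one core; the permutation
calibration (500 replicates of a 150-row null at 200 permutations) in
about 4 minutes; Hs recovery (4 variance ratios x 100 seeds) in seconds.
Every stochastic step takes an explicit seed, reruns of a configuration
are bit-identical for deterministic stages, and `run_pipeline()` logs each
stage with its seed to `run.log`.

## Known limitations

* Idealised propagation only: no wind, noise, ground effect, refraction or
  topography; spherical spreading assumes an elevated point source in an
  open habitat.
* The ISO 9613-1 closed forms carry their own stated accuracy envelope;
  conditions far outside it warn rather than error.
* Feature values are analyzer-specific: comparisons with tables produced
  by other extraction software are only meaningful at the level of trends
  across distance, not absolute numbers.
* The Hs-summation across PC scores assumes independent information per
  component; applying it to correlated raw features would overstate
  capacity.
* Embedding-before-split leakage, as discussed above, is replicated from
  the protocol rather than corrected.
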