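# aukprop

Does the individual identity encoded in a seabird's social call survive the
trip through hundreds of metres of Arctic air? `aukprop` answers the
question at the desk: it takes calibrated call recordings (or generates
synthetic calls with known ground truth), filters them exactly as the
atmosphere would, and measures how much caller-identity information the
standard statistics of vocal-individuality research can still find at each
distance.

The package is built around the little auk (*Alle alle*) study system —
social calls with fundamental frequencies of 500–2000 Hz, recorded at
48 kHz about 10 cm from birds inside nest crevices, propagated under
High-Arctic summer conditions — but every constant is configuration.

## What it computes

**Propagation.** Sound level at distance r from a 1 m reference follows
spherical spreading plus frequency-dependent atmospheric absorption:

    L(r, f) = L(1 m, f) − 20 log10(r) − α(f) · (r − 1)

with α(f) in dB/m from the ISO 9613-1 closed forms (molecular relaxation of
O₂ and N₂, driven by temperature, pressure and humidity). Waveforms are
attenuated by per-bin magnitude scaling of a single FFT and re-synthesised,
so one recorded call becomes a "modelled call" at each of the ten grid
distances 1, 2, 4, 10, 21, 46, 100, 215, 464, 1000 m under each month's
mean conditions — 40 modelled calls per source call.

**Levels.** End-to-end calibration from a reference tone; apparent sound
pressure levels (peak, and RMS over the 95 %-energy window); 1 m source
levels via SL = ASPL − 20·log10(r₀/r_meas); hierarchical population
summaries and a Welch comparison between call types.

**Features.** A 15-parameter feature set per call (duration, AM depth and
rates, frame RMS, cepstral peak prominence, dominant and peak frequency,
pitch and FM depth, spectral quartiles, centroid, slope) from a 5 ms-step
Gaussian-window STFT with pitch search restricted to 500–2000 Hz.

**Individuality statistics.** Kaiser–Meyer–Olkin adequacy; PCA with Kaiser
retention; nested permuted discriminant function analysis with a control
factor and seeded permutations; Beecher's information statistic
HSᵢ = log₂√((F + n − 1)/n) summed over components, with round(2^Hs) as the
theoretical number of distinguishable individuals; supervised 2-D
embedding + class-weighted SVM accuracy per distance, with an OLS test of
accuracy against log10(distance).

## A worked example

```r
library(aukprop)

# three synthetic individuals, one call each, July conditions
inds  <- make_individuals(3, seed = 7)
july  <- synth_meteo("July", seed = 7)
call  <- synthesize_call(inds[[1]], "single", seed = 1)

call
#> waveform: 14758 samples (0.307 s) @ 48000 Hz, calibration offset 80.03 dB
#>   [ind01_single_s1]

aspl_peak(call)                       # dB re 20 uPa at the 10 cm microphone
#> [1] 69.57663
source_level(aspl_peak(call), 0.1)    # back-calculated 1 m source level
#> [1] 49.57663

att <- attenuate_waveform(call, 215, july)
round(extract_features(call)[, c("pitch_mean", "q50", "spec_centroid_mean")], 1)
#>   pitch_mean    q50 spec_centroid_mean
#> 1     1412.1 1423.6             1884.8
round(extract_features(att)[, c("pitch_mean", "q50", "spec_centroid_mean")], 1)
#>   pitch_mean    q50 spec_centroid_mean
#> 1     1412.2 1414.1             1690.8
```

The pitch is untouched by 215 m of atmosphere while the spectral centroid
has slid down — the fingerprint of absorption acting as a low-pass filter,
and the mechanism by which F0-borne identity cues survive distance.

The full chain — synthesis, propagation over the 4 × 10 month/distance
grid, feature extraction, cleaning, PCA, per-distance pDFA, Beecher's Hs
and SVM accuracy — runs from one configuration object:

```r
res <- run_pipeline(run_config(mode = "synthetic", n_individuals = 6,
                               calls_per_individual = 8,
                               call_type = "single",
                               n_permutations = 200, seed = 101))
res$pdfa_by_distance   # observed vs chance classification per distance
res$hs_by_distance     # information content (bits) per distance
res$accuracy$trend     # accuracy ~ log10(distance) slope and p-value
```

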