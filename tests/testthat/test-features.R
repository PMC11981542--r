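test_that("the spectrogram localises tones, silence and chirps", {
  sg <- frame_spectrogram(tone_wave(1000))
  peaks <- sg$freq[apply(sg$mag, 2, which.max)]
  df <- sg$freq[2] - sg$freq[1]
  expect_true(all(abs(peaks - 1000) <= df))
  expect_error(frame_spectrogram(tone_wave(dur = 0.01)), "shorter")
  # silence: no frame within the dynamic range of anything
  z <- waveform(numeric(SR %/% 2), SR)
  expect_equal(measure_duration(frame_spectrogram(z)), NA_real_)
  # chirp: argmax frequency rises monotonically
  sgc <- frame_spectrogram(chirp_wave())
  pc <- sgc$freq[apply(sgc$mag, 2, which.max)]
  interior <- pc[5:(length(pc) - 5)]
  expect_true(all(diff(interior) >= -df))
  expect_gt(interior[length(interior)], interior[1])
})

test_that("duration spans first to last non-silent frame", {
  step_s <- 0.005
  w <- tone_wave(1000, dur = 0.4)
  expect_equal(measure_duration(frame_spectrogram(w)), 0.4,
               tolerance = 0.05)
  expect_equal(measure_duration(frame_spectrogram(pad_wave(w))), 0.4,
               tolerance = 0.05)
  # two bursts with a 0.2 s gap: duration spans the gap
  burst <- tone_wave(1000, dur = 0.1)$samples
  two <- waveform(c(burst, numeric(round(0.2 * SR)), burst), SR)
  expect_equal(measure_duration(frame_spectrogram(two)), 0.4,
               tolerance = 0.06)
})

test_that("amplitude modulation depth and rate are recovered", {
  sg <- function(w) frame_spectrogram(w)
  full <- am_tone_wave(rate = 10, depth = 1)
  am_full <- amplitude_modulation(full, sg(full))
  expect_equal(am_full$am_env_dep_mean, 1, tolerance = 0.1)
  expect_equal(am_full$am_env_freq_mean, 10, tolerance = 1)
  pure <- tone_wave(1000, dur = 1)
  expect_lt(amplitude_modulation(pure, sg(pure))$am_env_dep_mean, 0.05)
  half <- am_tone_wave(rate = 25, depth = 0.5)
  am_half <- amplitude_modulation(half, sg(half))
  expect_equal(am_half$am_env_dep_mean, 0.5, tolerance = 0.1)
  expect_equal(am_half$am_ms_freq_mean, 25, tolerance = 2)
})

test_that("pitch tracking recovers tones, rejects out-of-band signals", {
  pc <- pitch_contour(frame_spectrogram(tone_wave(1000)))
  expect_equal(pc$pitch_mean, 1000, tolerance = 10)
  expect_lt(pc$fm_dep_mean, 2)
  # below the search floor: unvoiced everywhere
  low <- pitch_contour(frame_spectrogram(tone_wave(300)))
  expect_false(any(low$voiced))
  expect_true(is.na(low$pitch_mean))
  # vibrato: mean recovered, nonzero modulation depth
  t <- seq(0, 0.6, by = 1 / SR)
  phase <- 2 * pi * cumsum(1000 + 100 * sin(2 * pi * 5 * t)) / SR
  vib <- pitch_contour(frame_spectrogram(waveform(0.5 * sin(phase), SR)))
  expect_equal(vib$pitch_mean, 1000, tolerance = 30)
  expect_gt(vib$fm_dep_mean, 1)
})

test_that("spectral descriptors match closed-form expectations", {
  sg <- frame_spectrogram(tone_wave(1000))
  pc <- pitch_contour(sg)
  d <- spectral_descriptors(sg, pc)
  df <- sg$freq[2] - sg$freq[1]
  for (v in c("q25", "q50", "q75", "peak_freq_mean"))
    expect_equal(d[[v]], 1000, tolerance = 1.5 * df)
  expect_equal(d$spec_centroid_mean, 1000, tolerance = 3 * df)
  expect_equal(d$dom_mean, 1000, tolerance = 1.5 * df)
  # white noise: flat spectrum
  nz <- noise_wave(dur = 1, seed = 21)
  sgn <- frame_spectrogram(nz)
  dn <- spectral_descriptors(sgn, pitch_contour(sgn))
  expect_equal(dn$q50, SR / 4, tolerance = 0.05 * SR / 4)
  expect_equal(dn$spec_slope_mean, 0, tolerance = 0.5)
  # two spectral lines: hand-computed first moment, dominant = lower line
  t <- seq(0, 0.5, by = 1 / SR)
  two <- waveform(0.5 * sin(2 * pi * 1000 * t) +
                  0.5 * 10^(-10 / 20) * sin(2 * pi * 4000 * t), SR)
  sg2 <- frame_spectrogram(two)
  d2 <- spectral_descriptors(sg2, pitch_contour(sg2))
  p_hi <- 10^(-10 / 10)
  centroid_expected <- (1000 + 4000 * p_hi) / (1 + p_hi)
  expect_equal(d2$spec_centroid_mean, centroid_expected, tolerance = 30)
  expect_equal(d2$dom_mean, 1000, tolerance = 1.5 * df)
  # periodicity: a harmonic comb ripples the spectrum, so its cepstral peak
  # stands clearly above that of noise (a lone tone has no comb to find)
  harm <- waveform(rowSums(sapply(1:8, function(h)
    (0.4 / h) * sin(2 * pi * 800 * h * t))), SR)
  sgh <- frame_spectrogram(harm)
  dh <- spectral_descriptors(sgh, pitch_contour(sgh))
  expect_gt(dh$cpp_mean, dn$cpp_mean + 3)
})

test_that("extraction returns the 15 canonical fields, deterministically", {
  ind <- make_individuals(2, seed = 8)
  w <- synthesize_call(ind[[1]], "classic", seed = 4)
  f <- extract_features(w)
  expect_equal(names(f), feature_names())
  expect_equal(ncol(f), 15)
  expect_identical(extract_features(w), f)
  # silence: everything missing
  fz <- extract_features(waveform(numeric(SR), SR))
  expect_true(all(is.na(unlist(fz))))
  # quantile ordering holds whenever present
  expect_true(f$q25 <= f$q50 && f$q50 <= f$q75)
  expect_true(f$pitch_mean >= 500 && f$pitch_mean <= 2000)
  expect_true(f$am_env_dep_mean >= 0 && f$am_env_dep_mean <= 1)
})

test_that("spectral and pitch features are scale-invariant", {
  ind <- make_individuals(2, seed = 8)
  w <- synthesize_call(ind[[2]], "single", seed = 9)
  half <- waveform(w$samples * 0.5, w$sample_rate)
  f1 <- extract_features(w)
  f2 <- extract_features(half)
  for (v in setdiff(feature_names(), "ampl_mean"))
    expect_equal(f2[[v]], f1[[v]], tolerance = 1e-6, label = v)
  expect_equal(f2$ampl_mean, f1$ampl_mean / 2, tolerance = 1e-6)
})

test_that("attenuation shifts spectral balance but spares the fundamental", {
  ind <- make_individuals(1, seed = 12)
  w <- synthesize_call(ind[[1]], "single", seed = 2)
  cond <- synth_meteo("July", seed = 1)
  feats <- lapply(as.numeric(distance_grid()), function(d)
    extract_features(attenuate_waveform(w, d, cond)))
  cents <- vapply(feats, `[[`, numeric(1), "spec_centroid_mean")
  q75 <- vapply(feats, `[[`, numeric(1), "q75")
  pitch <- vapply(feats, `[[`, numeric(1), "pitch_mean")
  expect_true(all(diff(cents) <= cents[-length(cents)] * 0.01))
  expect_true(all(diff(q75) <= q75[-length(q75)] * 0.01))
  expect_true(all(abs(pitch - pitch[1]) / pitch[1] < 0.02))
})
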