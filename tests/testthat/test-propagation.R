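test_that("the truncated log grid reproduces the canonical distance list", {
  expect_equal(as.numeric(distance_grid()),
               c(1, 2, 4, 10, 21, 46, 100, 215, 464, 1000))
  expect_equal(as.numeric(distance_grid(n_points = 2)), c(1, 1000))
  expect_error(distance_grid(1), "n_points")
  expect_error(distance_grid(d_min = 0.5), "d_min")
  expect_error(distance_grid(d_max = 1), "exceed")
})

test_that("propagation gain combines spreading and absorption correctly", {
  cond <- arctic_conditions()
  f <- c(100, 500, 1000, 4000, 12000)
  expect_equal(propagation_gain(f, 1, cond), rep(0, length(f)))
  # pure spherical spreading in the zero-frequency limit
  expect_equal(propagation_gain(0, 10, cond), -20)
  # composition of spreading with the pinned absorption coefficient
  alpha <- absorption_coefficient(1000, cond)
  expect_equal(propagation_gain(1000, 1000, cond), -60 - alpha * 999)
  # strictly decreasing in distance, decreasing in frequency
  g_r <- propagation_gain(1000, as.numeric(distance_grid()), cond)
  expect_true(all(diff(g_r) < 0))
  g_f <- propagation_gain(c(500, 2000, 8000), 100, cond)
  expect_true(all(diff(g_f) < 0))
  expect_error(propagation_gain(1000, 0.5, cond), "reference_distance")
})

test_that("attenuation at the reference distance is the identity", {
  w <- noise_wave(dur = 0.2, offset = 90)
  out <- attenuate_waveform(w, 1, arctic_conditions())
  expect_lt(max(abs(out$samples - w$samples)), 1e-9)
  expect_equal(out$sample_rate, w$sample_rate)
  expect_equal(out$calibration_offset, w$calibration_offset)
  expect_equal(length(out), length(w))
})

test_that("per-band level drop on white noise matches the closed-form gain", {
  w <- noise_wave(dur = 1, seed = 7)
  cond <- arctic_conditions()
  out <- attenuate_waveform(w, 100, cond)
  n <- length(w$samples)
  f <- (seq_len(n %/% 2) - 1) * w$sample_rate / n
  p_in <- Mod(stats::fft(w$samples)[seq_len(n %/% 2)])^2
  p_out <- Mod(stats::fft(out$samples)[seq_len(n %/% 2)])^2
  for (fc in c(250, 500, 1000, 2000, 4000)) {
    band <- f >= fc / 2^(1 / 6) & f <= fc * 2^(1 / 6)
    drop <- 10 * log10(sum(p_out[band]) / sum(p_in[band]))
    expect_lt(abs(drop - propagation_gain(fc, 100, cond)), 0.1)
  }
})

test_that("attenuation is linear and strictly level-reducing", {
  cond <- arctic_conditions()
  w1 <- tone_wave(800, dur = 0.3)
  w2 <- noise_wave(dur = 0.3, seed = 3)
  n <- min(length(w1), length(w2))
  sum_wave <- waveform(w1$samples[1:n] + w2$samples[1:n], SR)
  a_sum <- attenuate_waveform(sum_wave, 46, cond)$samples
  a_sep <- attenuate_waveform(waveform(w1$samples[1:n], SR), 46, cond)$samples +
    attenuate_waveform(waveform(w2$samples[1:n], SR), 46, cond)$samples
  expect_lt(max(abs(a_sum - a_sep)), 1e-9)
  # broadband RMS decreases strictly with distance for any input
  rms <- vapply(as.numeric(distance_grid()), function(d)
    sqrt(mean(attenuate_waveform(w2, d, cond)$samples^2)), numeric(1))
  expect_true(all(diff(rms) < 0))
  expect_true(all(rms < sqrt(mean(w2$samples^2))))
})

test_that("high frequencies are lost preferentially with distance", {
  cond <- arctic_conditions()
  w <- noise_wave(dur = 0.5, seed = 11)
  cents <- vapply(as.numeric(distance_grid()), function(d) {
    sg <- frame_spectrogram(attenuate_waveform(w, d, cond))
    spectral_descriptors(sg, list(f0 = rep(NA_real_, ncol(sg$mag)),
                                  voiced = logical(ncol(sg$mag))))$spec_centroid_mean
  }, numeric(1))
  expect_true(all(diff(cents) <= abs(cents[-length(cents)]) * 0.01))
  expect_lt(cents[10], cents[1])
})

test_that("silent input is returned unchanged with a warning", {
  z <- waveform(numeric(1000), SR)
  expect_warning(out <- attenuate_waveform(z, 100, arctic_conditions()),
                 "silent")
  expect_identical(out$samples, z$samples)
})

test_that("batch propagation yields one output per call-month-distance", {
  ind <- make_individuals(1, seed = 3)
  call <- synthesize_call(ind[[1]], "single", seed = 1)
  months <- lapply(stats::setNames(nm = c("May", "June", "July", "August")),
                   synth_meteo, seed = 3)
  dir <- tempfile("batch_")
  man <- batch_propagate(list(c1 = call), months, distance_grid(), dir)
  expect_equal(nrow(man), 40)
  expect_true(all(man$status == "ok"))
  expect_true(all(file.exists(man$path)))
  expect_true(all(man$broadband_gain_dB <= 1e-9))
  expect_true(all(man$broadband_gain_dB[man$distance_m > 1] < 0))
  # identity-distance grid reproduces the inputs
  man1 <- batch_propagate(list(a = call, b = call), months["May"], 1, NULL)
  expect_equal(nrow(man1), 2)
  expect_lt(max(abs(man1$wave[[1]]$samples - call$samples)), 1e-9)
  expect_error(batch_propagate(list(c1 = call), list(), distance_grid(), dir),
               "conditions")
  unlink(dir, recursive = TRUE)
})

test_that("WAV files round-trip through write and read", {
  w <- noise_wave(dur = 0.1, seed = 5, offset = 80)
  p <- tempfile(fileext = ".wav")
  write_wav(w, p)
  back <- read_wav(p, calibration_offset = 80)
  expect_equal(back$sample_rate, w$sample_rate)
  expect_lt(max(abs(back$samples - w$samples)), 1e-6)  # float32 precision
  write_wav(w, p, format = "pcm16")
  back16 <- read_wav(p)
  expect_lt(max(abs(back16$samples - w$samples)), 1 / 32000)
  file.remove(p)
})
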