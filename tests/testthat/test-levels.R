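test_that("calibration offset matches its closed form and round-trips", {
  full_sine <- tone_wave(1000, dur = 1, amp = 1)
  off <- calibration_offset(full_sine, known_level = 94)
  expect_equal(off, 94 + 20 * log10(sqrt(2)), tolerance = 1e-4)
  # round trip: calibrating a tone with its own measured level is exact
  w <- tone_wave(1000, dur = 0.5, amp = 0.37)
  off2 <- calibration_offset(w, known_level = 81.3)
  cal <- calibrate(w, off2)
  expect_equal(20 * log10(sqrt(mean(cal$samples^2))) + cal$calibration_offset,
               81.3, tolerance = 1e-9)
  expect_equal(aspl_rms95(cal), 81.3, tolerance = 0.01)
  # halving the recorded amplitude shifts the offset by exactly 20*log10(2)
  half <- tone_wave(1000, dur = 1, amp = 0.5)
  expect_equal(calibration_offset(half, 94) - calibration_offset(full_sine, 94),
               20 * log10(2))
  expect_error(calibration_offset(waveform(numeric(SR), SR), 94), "silent")
  expect_error(calibration_offset(tone_wave(dur = 0.01), 94), "0.1 s")
})

test_that("peak level is the calibrated maximum magnitude", {
  w <- calibrate(tone_wave(1000, amp = 0.25), 100)
  expect_equal(as.numeric(aspl_peak(w)), 20 * log10(0.25) + 100,
               tolerance = 1e-6)
  w2 <- calibrate(waveform(2 * 0.25 * sin(2 * pi * 1000 *
                                          seq(0, 0.4, by = 1 / SR)), SR), 100)
  expect_equal(as.numeric(aspl_peak(w2)) - as.numeric(aspl_peak(w)),
               20 * log10(2), tolerance = 1e-6)
  # a click concentrates amplitude: higher peak than same-RMS noise
  click <- numeric(SR %/% 10); click[100] <- 1
  nz <- noise_wave(dur = 0.1, seed = 9)$samples
  nz <- nz * sqrt(mean(click^2) / mean(nz^2))
  expect_gt(as.numeric(aspl_peak(calibrate(waveform(click, SR), 90))),
            as.numeric(aspl_peak(calibrate(waveform(nz, SR), 90))))
  # clipped signals are flagged
  clipped <- calibrate(waveform(c(numeric(100), 1, numeric(100)), SR), 90)
  expect_true(isTRUE(attr(aspl_peak(clipped), "clipped")))
  expect_identical(as.numeric(aspl_peak(calibrate(waveform(numeric(100), SR),
                                                  90))), -Inf)
})

test_that("95%-energy RMS ignores silence and matches the brute-force scan", {
  w <- calibrate(tone_wave(1000, dur = 0.5, amp = 0.4), 95)
  expect_equal(aspl_rms95(w), 20 * log10(0.4 / sqrt(2)) + 95, tolerance = 0.1)
  # padding with silence leaves the level unchanged
  expect_equal(aspl_rms95(pad_wave(w)), aspl_rms95(w), tolerance = 0.1)
  # ramped tone pinned by the independent cumulative-energy scan
  t <- seq(0, 0.5, by = 1 / SR)
  ramp <- calibrate(waveform((t / 0.5) * sin(2 * pi * 900 * t), SR), 88)
  expect_equal(aspl_rms95(ramp),
               20 * log10(rms95_bruteforce(ramp$samples)) + 88,
               tolerance = 1e-9)
})

test_that("peak level never falls below the 95%-energy RMS level", {
  for (seed in 1:5) {
    w <- calibrate(noise_wave(dur = 0.2, seed = seed), 90)
    expect_gte(as.numeric(aspl_peak(w)), aspl_rms95(w))
  }
  w <- calibrate(am_tone_wave(rate = 15), 90)
  expect_gte(as.numeric(aspl_peak(w)), aspl_rms95(w))
})

test_that("source level back-calculation follows spherical spreading", {
  expect_equal(source_level(83, 0.1), 63)
  expect_equal(source_level(70, 1), 70)
  expect_equal(source_level(60, 0.5), 60 - 20 * log10(1 / 0.5))
  expect_error(source_level(60, 0), "positive")
})

test_that("level summaries average hierarchically and compare call types", {
  # individual A has many quiet calls: a call-wise mean would differ
  d <- data.frame(
    call_id = sprintf("c%02d", 1:12),
    individual = c(rep("A", 6), rep("B", 2), rep("C", 2), rep("D", 2)),
    call_type = c(rep("classic", 8), rep("single", 4)),
    peak_level = c(rep(50, 6), rep(70, 2), rep(60, 2), rep(58, 2)),
    rms_level = c(rep(40, 6), rep(60, 2), rep(50, 2), rep(48, 2)))
  s <- summarize_levels(d)
  classic <- s$population[s$population$call_type == "classic" &
                          s$population$measure == "peak_level", ]
  expect_equal(classic$mean, mean(c(50, 70)))  # not the call-wise 55
  expect_false(isTRUE(all.equal(classic$mean,
                                mean(d$peak_level[d$call_type == "classic"]))))
  # one call per individual: the individual mean is the call's value
  one <- s$individual_means
  expect_equal(one$peak_level[one$individual == "C"], 60)

  # identical groups: no difference, p near 1
  eq <- data.frame(call_id = sprintf("c%d", 1:8),
                   individual = rep(c("A", "B", "C", "D"), 2),
                   call_type = rep(c("classic", "single"), each = 4),
                   peak_level = rep(c(60, 61, 59, 60), 2) + rep(c(0, 0), each = 4),
                   rms_level = rep(c(50, 51, 49, 50), 2))
  s_eq <- summarize_levels(eq)
  expect_gt(s_eq$comparison$p_value[1], 0.9)
  expect_equal(s_eq$comparison$mean_diff[1], 0, tolerance = 1e-9)

  # large separated groups: clearly significant
  set.seed(1)
  big <- data.frame(call_id = sprintf("c%d", 1:40),
                    individual = sprintf("i%02d", 1:40),
                    call_type = rep(c("classic", "single"), each = 20),
                    peak_level = c(rnorm(20, 60, 0.5), rnorm(20, 54, 0.5)),
                    rms_level = c(rnorm(20, 45, 0.5), rnorm(20, 42, 0.5)))
  s_big <- summarize_levels(big)
  expect_lt(max(s_big$comparison$p_value), 0.001)

  # single-individual group: comparison skipped with a warning
  expect_warning(s1 <- summarize_levels(d[d$individual != "D", ]), "skipped")
  expect_null(s1$comparison)
})

test_that("attenuate + back-calculate round-trips the low-frequency level", {
  cond <- arctic_conditions()
  w <- calibrate(tone_wave(500, dur = 0.5, amp = 0.3), 80)
  r <- 100
  att <- attenuate_waveform(w, r, cond)
  recovered <- source_level(aspl_rms95(att), measurement_distance = r)
  expect_equal(recovered, aspl_rms95(w),
               tolerance = absorption_coefficient(500, cond) * r + 0.1)
})
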