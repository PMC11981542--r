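# signal fixtures built in code; all seeded and deterministic

SR <- 48000

tone_wave <- function(freq = 1000, dur = 0.4, amp = 0.5, sr = SR,
                      offset = NA_real_) {
  waveform(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr)), sr, offset)
}

noise_wave <- function(dur = 0.5, amp = 0.3, sr = SR, seed = 42,
                       offset = NA_real_) {
  set.seed(seed)
  waveform(amp * stats::runif(round(dur * sr) + 1L, -1, 1), sr, offset)
}

# sinusoidal AM with modulation index `depth`: envelope spans
# [1 - depth, 1 + depth], so (max - min)/(max + min) = depth
am_tone_wave <- function(carrier = 1000, rate = 10, depth = 1, dur = 1,
                         amp = 0.4, sr = SR) {
  t <- seq(0, dur, by = 1 / sr)
  env <- (1 + depth * sin(2 * pi * rate * t)) / (1 + depth)
  waveform(amp * env * sin(2 * pi * carrier * t), sr)
}

chirp_wave <- function(f0 = 500, f1 = 2000, dur = 0.5, amp = 0.5, sr = SR) {
  t <- seq(0, dur, by = 1 / sr)
  phase <- 2 * pi * cumsum(f0 + (f1 - f0) * t / dur) / sr
  waveform(amp * sin(phase), sr)
}

pad_wave <- function(wave, pad_s = 1) {
  z <- numeric(round(pad_s * wave$sample_rate))
  waveform(c(z, wave$samples, z), wave$sample_rate, wave$calibration_offset)
}

arctic_conditions <- function(t = 5, p_hPa = 1010, rh = 85, label = "test") {
  meteo_conditions(t, p_hPa, rh, label = label, pressure_unit = "hPa")
}
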