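#' Acoustic analysis settings
#'
#' Settings controlling short-time analysis and pitch search. Defaults match
#' the analysis protocol for little auk social calls: 60 dB dynamic range,
#' pitch search restricted to 500-2000 Hz, 5 ms step. The 40 ms
#' Gaussian-tapered window resolves a 500 Hz fundamental with a 20-period
#' margin; the 0.45 voicing threshold on the normalised autocorrelation peak
#' is conventional for clean harmonic signals. Both are configurable.
#'
#' @param dynamic_range dB below the maximum frame level above which a frame
#'   counts as non-silent (default 60).
#' @param pitch_floor,pitch_ceiling pitch search band in Hz (default
#'   500-2000).
#' @param step analysis step in ms (default 5).
#' @param window analysis window length in ms (default 40, Gaussian taper).
#' @param voicing_threshold minimum normalised autocorrelation peak for a
#'   frame to count as voiced (default 0.45).
#' @param dominance_threshold dB below the frame maximum within which a
#'   spectral peak counts as dominant (default 20).
#' @param env_cutoff low-pass cutoff in Hz for the amplitude envelope
#'   (default 100).
#' @param ms_band modulation-spectrum search band in Hz (default 5-200,
#'   clipped to the frame-rate Nyquist).
#' @return list of class `analysis_settings`.
#' @export
analysis_settings <- function(dynamic_range = 60, pitch_floor = 500,
                              pitch_ceiling = 2000, step = 5, window = 40,
                              voicing_threshold = 0.45,
                              dominance_threshold = 20,
                              env_cutoff = 100, ms_band = c(5, 200)) {
  if (pitch_floor >= pitch_ceiling) stop("pitch_floor must be < pitch_ceiling")
  if (step <= 0 || window <= 0) stop("step and window must be positive")
  if (dynamic_range <= 0) stop("dynamic_range must be positive")
  structure(list(dynamic_range = dynamic_range, pitch_floor = pitch_floor,
                 pitch_ceiling = pitch_ceiling, step = step, window = window,
                 voicing_threshold = voicing_threshold,
                 dominance_threshold = dominance_threshold,
                 env_cutoff = env_cutoff, ms_band = ms_band),
            class = "analysis_settings")
}

#' The 15 extracted acoustic parameters, in canonical order
#'
#' @return character vector of the 15 feature names produced by
#'   [extract_features()].
#' @export
feature_names <- function() {
  c("duration", "am_env_dep_mean", "am_env_freq_mean", "am_ms_freq_mean",
    "ampl_mean", "cpp_mean", "dom_mean", "fm_dep_mean", "peak_freq_mean",
    "pitch_mean", "q25", "q50", "q75", "spec_centroid_mean",
    "spec_slope_mean")
}

#' Short-time magnitude spectrogram
#'
#' Gaussian-windowed STFT at the analysis step, the substrate for every
#' frame-based feature. Frame RMS is measured on the un-windowed frame so
#' the silence criterion is independent of the taper.
#'
#' @param wave a [waveform()].
#' @param settings an [analysis_settings()].
#' @return list of class `call_spectrogram`: `mag` (linear magnitude,
#'   frequency x frame), `freq` (Hz), `t` (frame centres, s), `frame_rms`,
#'   `frames` (windowed time-domain frames), `sample_rate`, `settings`.
#' @export
frame_spectrogram <- function(wave, settings = analysis_settings()) {
  stopifnot(inherits(wave, "waveform"))
  sr <- wave$sample_rate
  win_n <- round(settings$window / 1000 * sr)
  step_n <- max(1L, round(settings$step / 1000 * sr))
  if (length(wave$samples) < win_n) stop("signal shorter than analysis window")
  # half-window zero padding so frame centres span the whole signal: frame
  # timing then resolves call edges to the step, not the window
  half <- win_n %/% 2L
  x <- c(numeric(half), wave$samples, numeric(half))
  starts <- seq.int(1L, length(x) - win_n + 1L, by = step_n)
  idx <- outer(seq_len(win_n) - 1L, starts, `+`)
  fr <- matrix(x[idx], nrow = win_n)
  # silence criterion on the central step-length slice, so a frame is "on"
  # exactly when its own time slot holds energy (no window-length smearing)
  c0 <- (win_n - step_n) %/% 2L
  frame_rms <- sqrt(colMeans(fr[(c0 + 1L):(c0 + step_n), , drop = FALSE]^2))
  g <- exp(-0.5 * ((seq_len(win_n) - (win_n + 1) / 2) / (win_n / 6))^2)
  frw <- fr * g
  nfft <- 2^ceiling(log2(win_n))
  pad <- matrix(0, nrow = nfft, ncol = ncol(frw))
  pad[seq_len(win_n), ] <- frw
  spec <- stats::mvfft(pad)
  nb <- nfft %/% 2L + 1L
  structure(list(mag = abs(spec[seq_len(nb), , drop = FALSE]),
                 freq = (seq_len(nb) - 1L) * sr / nfft,
                 t = (starts - 1L + win_n / 2 - half) / sr,
                 frame_rms = frame_rms, frames = fr,
                 sample_rate = sr, nfft = nfft, settings = settings),
            class = "call_spectrogram")
}

# frames within dynamic_range dB of the loudest frame
nonsilent_frames <- function(sg) {
  mx <- max(sg$frame_rms)
  if (mx == 0) return(logical(length(sg$frame_rms)))
  sg$frame_rms >= mx * 10^(-sg$settings$dynamic_range / 20)
}

#' Call duration from non-silent frames
#'
#' Time from the beginning of the first non-silent STFT frame to the end of
#' the last non-silent frame, where non-silent means frame RMS within the
#' dynamic range of the loudest frame. Interior silent gaps (between
#' syllables) are spanned, not subtracted.
#'
#' @param sg a [frame_spectrogram()].
#' @return duration in seconds, or `NA` if no frame is non-silent.
#' @export
measure_duration <- function(sg) {
  ns <- which(nonsilent_frames(sg))
  if (!length(ns)) return(NA_real_)
  (ns[length(ns)] - ns[1L] + 1L) * sg$settings$step / 1000
}

# runs of TRUE in a logical vector -> matrix of (start, end)
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Amplitude-modulation measures
#'
#' Estimates modulation depth and rate from two independent routes:
#' a smoothed amplitude envelope (rectified signal low-passed at the
#' envelope cutoff) and the modulation spectrum (FFT across time of
#' spectrogram rows).
#'
#' Depth is measured per non-silent segment (active envelope runs, with
#' sub-50 ms dropouts such as modulation zeros merged) as the robust spread
#' of the envelope, `(q98 - q02) / (q98 + q02)`, which estimates
#' `(env_max - env_min) / (env_max + env_min)`: 0 for a steady tone, the
#' modulation index for sinusoidal AM, 1 at full modulation. Segment edges
#' are trimmed by the envelope-filter settling time before the quantiles are
#' taken. The envelope rate is the dominant frequency of the mean-removed
#' segment envelope; it is reported missing when depth < 0.05 (no
#' modulation to time). The modulation-spectrum rate averages the spectral
#' argmax over energetic spectrogram rows.
#'
#' @param wave a [waveform()].
#' @param sg a [frame_spectrogram()] of the same wave.
#' @return named list: `am_env_dep_mean` (0-1), `am_env_freq_mean` (Hz),
#'   `am_ms_freq_mean` (Hz).
#' @export
amplitude_modulation <- function(wave, sg) {
  st <- sg$settings
  sr <- wave$sample_rate
  out <- list(am_env_dep_mean = NA_real_, am_env_freq_mean = NA_real_,
              am_ms_freq_mean = NA_real_)
  if (is_silent(wave)) return(out)
  bf <- signal::butter(4, min(0.99, st$env_cutoff / (sr / 2)), type = "low")
  env <- signal::filtfilt(bf, abs(wave$samples))
  env[env < 0] <- 0
  act <- env >= max(env) * 10^(-st$dynamic_range / 20)
  # merge sub-50 ms dropouts (e.g. the zeros of full modulation) so one
  # syllable stays one segment; real inter-syllable gaps stay splits
  gap <- round(0.05 * sr)
  gaps <- runs_of(!act)
  for (g in seq_len(nrow(gaps)))
    if (gaps[g, "end"] - gaps[g, "start"] + 1L < gap &&
        gaps[g, "start"] > 1L && gaps[g, "end"] < length(act))
      act[gaps[g, "start"]:gaps[g, "end"]] <- TRUE
  segs <- runs_of(act)
  min_len <- round(0.05 * sr)
  segs <- segs[segs[, "end"] - segs[, "start"] + 1L >= min_len, , drop = FALSE]
  if (nrow(segs)) {
    settle <- round(0.015 * sr)  # envelope-filter settling time
    depths <- apply(segs, 1L, function(s) {
      e <- env[s[1L]:s[2L]]
      if (length(e) > 3L * settle) e <- e[settle:(length(e) - settle + 1L)]
      q <- stats::quantile(e, c(0.02, 0.98), names = FALSE)
      if (sum(q) == 0) 0 else (q[2L] - q[1L]) / (q[2L] + q[1L])
    })
    out$am_env_dep_mean <- min(1, mean(depths))
    # envelope rate from the longest segment
    s <- segs[which.max(segs[, "end"] - segs[, "start"]), ]
    e <- env[s[1L]:s[2L]]
    e <- e - mean(e)
    nz <- 2^ceiling(log2(length(e) * 4L))
    sp <- abs(stats::fft(c(e, numeric(nz - length(e)))))[seq_len(nz %/% 2L)]
    fq <- (seq_len(nz %/% 2L) - 1L) * (sr / nz)
    band <- fq >= 2 & fq <= st$env_cutoff
    if (any(band) && out$am_env_dep_mean >= 0.05)
      out$am_env_freq_mean <- fq[band][which.max(sp[band])]
  }
  # modulation spectrum: FFT of each energetic spectrogram row across frames
  ns <- nonsilent_frames(sg)
  if (sum(ns) >= 8L) {
    frate <- 1000 / st$step
    m <- sg$mag[, ns, drop = FALSE]
    row_e <- rowMeans(m^2)
    rows <- which(row_e >= max(row_e) * 10^(-st$dynamic_range / 10))
    nt <- ncol(m)
    nz <- 2^ceiling(log2(nt * 4L))
    mr <- m[rows, , drop = FALSE] - rowMeans(m[rows, , drop = FALSE])
    sp <- abs(stats::mvfft(t(cbind(mr, matrix(0, length(rows), nz - nt)))))
    fq <- (seq_len(nz) - 1L) * frate / nz
    band <- fq >= st$ms_band[1L] & fq <= min(st$ms_band[2L], frate / 2)
    if (any(band)) {
      peaks <- apply(sp[band, , drop = FALSE], 2L, which.max)
      out$am_ms_freq_mean <- mean(fq[band][peaks])
    }
  }
  out
}

#' Pitch contour by frame-wise autocorrelation
#'
#' Per-frame fundamental-frequency estimates from the normalised
#' autocorrelation of each analysis frame, with the lag search restricted to
#' the configured pitch band and parabolic interpolation of the peak lag.
#' A frame is voiced when its normalised autocorrelation peak reaches the
#' voicing threshold; the voiced contour is post-processed with a 3-point
#' running median.
#'
#' @param sg a [frame_spectrogram()].
#' @return list: `f0` (per-frame Hz, `NA` when unvoiced), `voiced` (logical),
#'   `pitch_mean` (Hz over voiced frames), `fm_dep_mean` (mean absolute
#'   frame-to-frame excursion, Hz).
#' @export
pitch_contour <- function(sg) {
  st <- sg$settings
  sr <- sg$sample_rate
  ns <- nonsilent_frames(sg)
  n_fr <- ncol(sg$frames)
  f0 <- rep(NA_real_, n_fr)
  lag_min <- max(2L, floor(sr / st$pitch_ceiling))
  lag_max <- ceiling(sr / st$pitch_floor)
  win_n <- nrow(sg$frames)
  if (lag_max >= win_n) stop("analysis window too short for pitch_floor")
  # batched autocorrelation via FFT
  nz <- 2^ceiling(log2(2L * win_n))
  fr <- sg$frames - rep(colMeans(sg$frames), each = win_n)
  pad <- matrix(0, nz, n_fr)
  pad[seq_len(win_n), ] <- fr
  P <- abs(stats::mvfft(pad))^2
  r <- Re(stats::mvfft(P, inverse = TRUE)) / nz
  r0 <- r[1L, ]
  for (j in which(ns & r0 > 0)) {
    rj <- r[seq_len(lag_max + 2L), j] / r0[j]
    seg <- rj[(lag_min + 1L):(lag_max + 2L)]
    # only interior local maxima qualify: a band-edge maximum means the true
    # period lies outside the search band (e.g. an out-of-band tone)
    nloc <- length(seg) - 1L
    locs <- which(seg[2:nloc] >= seg[1:(nloc - 1L)] &
                  seg[2:nloc] > seg[3:(nloc + 1L)]) + 1L
    if (!length(locs)) next
    k <- locs[which.max(seg[locs])]
    if (seg[k] < st$voicing_threshold) next
    lag <- lag_min + k - 1L
    # parabolic interpolation around the peak
    if (lag > lag_min && lag < lag_max) {
      y1 <- rj[lag]; y2 <- rj[lag + 1L]; y3 <- rj[lag + 2L]
      den <- y1 - 2 * y2 + y3
      if (den != 0) lag <- lag + 0.5 * (y1 - y3) / den
    }
    cand <- sr / lag
    if (cand >= st$pitch_floor && cand <= st$pitch_ceiling) f0[j] <- cand
  }
  voiced <- !is.na(f0)
  if (any(voiced)) {
    v <- which(voiced)
    sm <- f0
    for (i in seq_along(v)) {
      nb <- v[abs(v - v[i]) <= 1L]
      sm[v[i]] <- stats::median(f0[nb])
    }
    f0 <- sm
    pitch_mean <- mean(f0[voiced])
    adj <- diff(which(voiced)) == 1L
    fm <- abs(diff(f0[voiced]))[adj]
    fm_dep_mean <- if (length(fm)) mean(fm) else 0
  } else {
    pitch_mean <- NA_real_
    fm_dep_mean <- NA_real_
  }
  list(f0 = f0, voiced = voiced, pitch_mean = pitch_mean,
       fm_dep_mean = fm_dep_mean)
}

#' Frame-averaged spectral descriptors
#'
#' Computes the spectral members of the feature set from the magnitude
#' spectrogram: power quantiles (Q25/Q50/Q75), spectral centroid, dB/kHz
#' spectral slope, cepstral peak prominence, lowest dominant frequency band,
#' peak frequency, and mean frame RMS. Quantiles and CPP are taken over
#' voiced frames when any exist (their Table-1 definition), falling back to
#' all non-silent frames for unvoiced signals; the rest use non-silent
#' frames.
#'
#' @param sg a [frame_spectrogram()].
#' @param pitch result of [pitch_contour()] on the same spectrogram.
#' @return named list: `cpp_mean`, `dom_mean`, `peak_freq_mean`, `q25`,
#'   `q50`, `q75`, `spec_centroid_mean`, `spec_slope_mean`, `ampl_mean`.
#' @export
spectral_descriptors <- function(sg, pitch = pitch_contour(sg)) {
  st <- sg$settings
  ns <- nonsilent_frames(sg)
  out <- list(cpp_mean = NA_real_, dom_mean = NA_real_,
              peak_freq_mean = NA_real_, q25 = NA_real_, q50 = NA_real_,
              q75 = NA_real_, spec_centroid_mean = NA_real_,
              spec_slope_mean = NA_real_, ampl_mean = NA_real_)
  if (!any(ns)) return(out)
  M <- sg$mag[, ns, drop = FALSE]
  f <- sg$freq
  P <- M^2
  tot <- colSums(P)
  ok <- tot > 0
  out$ampl_mean <- mean(sg$frame_rms[ns])
  out$peak_freq_mean <- mean(f[apply(M, 2L, which.max)])
  out$spec_centroid_mean <- mean((colSums(f * P) / tot)[ok])
  # slope: least-squares dB vs kHz, per frame (shared regressor)
  fk <- f / 1000
  dB <- pmax(20 * log10(sweep(M, 2L, apply(M, 2L, max), `/`) + 1e-12),
             -st$dynamic_range)
  fc <- fk - mean(fk)
  out$spec_slope_mean <- mean(colSums(fc * dB) / sum(fc^2))
  # dominant band: lowest local spectral peak within the dominance threshold
  thr <- 10^(-st$dominance_threshold / 20)
  nb <- nrow(M)
  dom <- apply(M, 2L, function(m) {
    pk <- which(m >= c(-Inf, m[-nb]) & m > c(m[-1L], Inf) & m >= max(m) * thr)
    if (length(pk)) f[pk[1L]] else NA_real_
  })
  out$dom_mean <- mean(dom, na.rm = TRUE)
  # quantiles of spectral power, per frame, averaged
  qframes <- if (any(pitch$voiced)) which(pitch$voiced & nonsilent_frames(sg)) else which(ns)
  Q <- sg$mag[, qframes, drop = FALSE]^2
  cum <- apply(Q, 2L, cumsum)
  qtot <- cum[nrow(cum), ]
  valid <- qtot > 0
  qat <- function(p) mean(vapply(which(valid), function(j)
    f[which(cum[, j] >= p * qtot[j])[1L]], numeric(1)))
  if (any(valid)) {
    out$q25 <- qat(0.25); out$q50 <- qat(0.50); out$q75 <- qat(0.75)
  }
  # cepstral peak prominence within the pitch quefrency band
  out$cpp_mean <- cpp_mean_frames(sg$mag[, qframes, drop = FALSE],
                                  sg$sample_rate, st)
  out
}

# mean CPP over frames: dB magnitude of the cepstrum (FFT of each frame's
# dB spectrum); peak in the pitch quefrency band measured against a
# regression line fitted over 0.1-10 ms quefrency (shared regressor,
# closed-form least squares).
cpp_mean_frames <- function(mag, sr, st) {
  mx <- apply(mag, 2L, max)
  keep <- mx > 0
  if (!any(keep)) return(NA_real_)
  mag <- mag[, keep, drop = FALSE]
  dB <- pmax(20 * log10(sweep(mag, 2L, mx[keep], `/`) + 1e-12),
             -st$dynamic_range)
  nb <- nrow(dB)
  full <- rbind(dB, dB[rev(seq.int(2L, nb - 1L)), , drop = FALSE])
  cep <- 20 * log10(Mod(stats::mvfft(full)) / nrow(full) + 1e-12)
  q <- (seq_len(nrow(full)) - 1L) / sr
  band <- which(q >= 1 / st$pitch_ceiling & q <= 1 / st$pitch_floor)
  base <- which(q >= 1e-4 & q <= 1e-2)
  if (!length(band) || length(base) < 2L) return(NA_real_)
  xc <- q[base] - mean(q[base])
  slope <- colSums(xc * cep[base, , drop = FALSE]) / sum(xc^2)
  intercept <- colMeans(cep[base, , drop = FALSE]) - slope * mean(q[base])
  k <- band[apply(cep[band, , drop = FALSE], 2L, which.max)]
  peak <- cep[cbind(k, seq_len(ncol(cep)))]
  mean(peak - (intercept + slope * q[k]))
}

#' Extract the 15-parameter acoustic feature set
#'
#' Runs the full frame-based analysis on one call and returns the 15
#' parameters of the canonical feature set (see [feature_names()]), with
#' `NA` wherever a parameter is undefined for the signal (e.g. pitch of an
#' unvoiced call). Deterministic for a fixed input; sub-analysis failures
#' yield missing fields, never an error, for any valid waveform.
#'
#' @param wave a [waveform()]; calibration is not required (levels are not
#'   part of this feature set).
#' @param settings an [analysis_settings()].
#' @return one-row data.frame of class `call_features` with the 15 columns
#'   of [feature_names()].
#' @examples
#' sr <- 48000
#' tone <- waveform(sin(2 * pi * 1000 * seq(0, 0.4, by = 1 / sr)), sr)
#' extract_features(tone)
#' @export
extract_features <- function(wave, settings = analysis_settings()) {
  stopifnot(inherits(wave, "waveform"))
  vals <- stats::setNames(as.list(rep(NA_real_, 15L)), feature_names())
  sg <- tryCatch(frame_spectrogram(wave, settings), error = function(e) NULL)
  if (!is.null(sg) && any(nonsilent_frames(sg))) {
    vals$duration <- measure_duration(sg)
    am <- tryCatch(amplitude_modulation(wave, sg),
                   error = function(e) NULL)
    if (!is.null(am)) vals[names(am)] <- am
    pc <- tryCatch(pitch_contour(sg), error = function(e) NULL)
    if (!is.null(pc)) {
      vals$pitch_mean <- pc$pitch_mean
      vals$fm_dep_mean <- pc$fm_dep_mean
    } else {
      pc <- list(f0 = rep(NA_real_, ncol(sg$mag)),
                 voiced = logical(ncol(sg$mag)))
    }
    sd_ <- tryCatch(spectral_descriptors(sg, pc), error = function(e) NULL)
    if (!is.null(sd_)) vals[names(sd_)] <- sd_
  }
  out <- as.data.frame(vals)[, feature_names()]
  class(out) <- c("call_features", "data.frame")
  out
}
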