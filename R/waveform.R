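#' Calibrated audio waveform
#'
#' Container for a mono audio signal in full-scale units together with the
#' mapping from full scale to absolute sound pressure level. The calibration
#' offset is defined so that a signal's level in dB re 20 uPa equals
#' \code{20*log10(rms(samples)) + calibration_offset}; it is established from
#' a reference tone with [calibration_offset()] and carried through every
#' propagation step so that modelled levels stay on an absolute scale.
#'
#' @param samples numeric vector of samples, nominally in \[-1, 1\].
#' @param sample_rate sampling rate in Hz (default 48000, the recording rate
#'   the pipeline assumes throughout; no resampling is performed anywhere).
#' @param calibration_offset dB offset mapping full-scale RMS to
#'   dB re 20 uPa; `NA` for uncalibrated audio.
#' @param provenance free-text identifier (file name, synthesis id, ...).
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate = 48000, calibration_offset = NA_real_,
                     provenance = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a waveform needs at least 2 samples")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         calibration_offset = as.numeric(calibration_offset)[1L],
         provenance = as.character(provenance)[1L]),
    class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("waveform: %d samples (%.3f s) @ %g Hz", length(x$samples),
              dur, x$sample_rate))
  if (is.finite(x$calibration_offset))
    cat(sprintf(", calibration offset %.2f dB", x$calibration_offset))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#'
#' @param wave a [waveform()].
#' @return duration in seconds.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$sample_rate

wave_rms <- function(wave) sqrt(mean(wave$samples^2))

is_silent <- function(wave) all(wave$samples == 0)

#' Read a RIFF/WAVE file
#'
#' Minimal WAV reader covering the formats this pipeline produces and
#' consumes: PCM 8/16/24/32-bit integer and IEEE float32/float64, any channel
#' count (channels are averaged to mono).
#'
#' @param path path to a `.wav` file.
#' @param calibration_offset optional dB calibration to attach.
#' @return A [waveform()].
#' @export
read_wav <- function(path, calibration_offset = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate     = readBin(fmt_raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path)
  fmt_code <- fmt$format
  if (fmt_code == 65534L) fmt_code <- if (fmt$bits >= 32L) 3L else 1L  # extensible
  x <- switch(as.character(fmt_code),
    "1" = {  # integer PCM
      bytes <- fmt$bits %/% 8L
      n <- length(data_raw) %/% bytes
      if (fmt$bits == 8L) {
        (as.integer(data_raw[seq_len(n)]) - 128) / 128
      } else if (fmt$bits == 24L) {
        m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        v <- readBin(data_raw, "integer", n, bytes, signed = TRUE, endian = "little")
        v / 2^(fmt$bits - 1L)
      }
    },
    "3" = {  # IEEE float
      bytes <- fmt$bits %/% 8L
      readBin(data_raw, "double", length(data_raw) %/% bytes, bytes, endian = "little")
    },
    stop("unsupported WAV format code: ", fmt$format))
  if (fmt$channels > 1L) {
    nfr <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nfr * fmt$channels)], nrow = fmt$channels))
  }
  waveform(x, fmt$rate, calibration_offset, provenance = basename(path))
}

#' Write a waveform to a RIFF/WAVE file
#'
#' Writes mono WAV as IEEE float32 (default) or PCM16. Float output is the
#' pipeline default: heavily attenuated signals sit 60+ dB below full scale
#' and would be destroyed by 16-bit re-quantization.
#'
#' @param wave a [waveform()].
#' @param path output path.
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- wave$samples
  sr <- as.integer(round(wave$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L
    payload_n <- length(x) * 4L
  } else {
    fmt_code <- 1L; bits <- 16L
    payload_n <- length(x) * 2L
  }
  block <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_n), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")            # mono
  writeBin(sr, con, 4L, endian = "little")
  writeBin(as.integer(sr * block), con, 4L, endian = "little")
  writeBin(as.integer(block), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_n), con, 4L, endian = "little")
  if (format == "float32") {
    writeBin(x, con, size = 4L, endian = "little")
  } else {
    v <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(v, con, size = 2L, endian = "little")
  }
  invisible(path)
}
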