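#' End-to-end calibration from a reference tone
#'
#' Derives the dB offset that maps full-scale RMS to absolute sound pressure
#' level, from a recording of a tone whose level was read on a sound level
#' meter: \code{offset = known_level - 20 log10(rms(samples))}. Attaching the
#' offset to the reference tone itself reproduces `known_level` exactly.
#'
#' @param tone an uncalibrated [waveform()] of the reference tone; at least
#'   0.1 s of steady signal.
#' @param known_level the meter reading in dB re 20 uPa.
#' @return the calibration offset in dB.
#' @examples
#' sr <- 48000
#' tone <- waveform(sin(2 * pi * 1000 * seq(0, 1, by = 1 / sr)), sr)
#' calibration_offset(tone, known_level = 94)
#' @export
calibration_offset <- function(tone, known_level) {
  stopifnot(inherits(tone, "waveform"), is.finite(known_level))
  if (wave_duration(tone) < 0.1)
    stop("reference tone must be at least 0.1 s long")
  r <- wave_rms(tone)
  if (r == 0) stop("reference tone is silent")
  known_level - 20 * log10(r)
}

#' Apply a calibration offset to a waveform
#'
#' @param wave a [waveform()].
#' @param offset dB offset from [calibration_offset()].
#' @return the calibrated [waveform()].
#' @export
calibrate <- function(wave, offset) {
  waveform(wave$samples, wave$sample_rate, offset, wave$provenance)
}

below_floor <- function() {
  structure(-Inf, below_floor = TRUE)
}

check_calibrated <- function(wave) {
  if (!is.finite(wave$calibration_offset))
    stop("waveform carries no calibration offset; see calibration_offset()")
}

#' Peak apparent sound pressure level
#'
#' Level of the highest absolute sample magnitude, in dB re 20 uPa:
#' \code{20 log10(max|x|) + calibration_offset}. Calls containing clipped
#' samples (|x| = 1) are flagged via the `"clipped"` attribute, since their
#' true peak is unknowable from the recording.
#'
#' @param wave a calibrated [waveform()].
#' @return peak level in dB re 20 uPa; `-Inf` with attribute `below_floor`
#'   for an all-zero signal.
#' @export
aspl_peak <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  check_calibrated(wave)
  pk <- max(abs(wave$samples))
  if (pk == 0) return(below_floor())
  out <- 20 * log10(pk) + wave$calibration_offset
  if (pk >= 1) attr(out, "clipped") <- TRUE
  out
}

# contiguous sample window holding the central 95 % of squared-sample energy
# (between the 2.5 % and 97.5 % points of cumulative energy)
energy_window_95 <- function(samples) {
  e <- cumsum(samples^2)
  tot <- e[length(e)]
  i1 <- which(e >= 0.025 * tot)[1L]
  i2 <- which(e >= 0.975 * tot)[1L]
  c(i1, i2)
}

#' RMS apparent sound pressure level (95 %-energy criterion)
#'
#' RMS level over the contiguous window between the 2.5 % and 97.5 % points
#' of cumulative squared-sample energy — the conventional M95 duration
#' criterion, which makes the measure insensitive to leading/trailing
#' silence — converted to dB re 20 uPa with the calibration offset.
#'
#' @param wave a calibrated [waveform()].
#' @return RMS level in dB re 20 uPa; `-Inf` (below floor) for silence.
#' @export
aspl_rms95 <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  check_calibrated(wave)
  if (is_silent(wave)) return(below_floor())
  w <- energy_window_95(wave$samples)
  r <- sqrt(mean(wave$samples[w[1L]:w[2L]]^2))
  20 * log10(r) + wave$calibration_offset
}

#' Back-calculate a source level at a reference distance
#'
#' Spherical-spreading back-calculation of the level a signal would have at
#' `reference_distance`, from its apparent level at `measurement_distance`:
#' \code{SL = aspl - 20 log10(reference_distance / measurement_distance)}.
#' For the conventional 0.1 m measurement and 1 m reference this subtracts
#' exactly 20 dB.
#'
#' @param aspl apparent sound pressure level in dB re 20 uPa.
#' @param measurement_distance distance at which `aspl` was measured, m (> 0).
#' @param reference_distance distance to reference the level to, m (> 0).
#' @return source level in dB re 20 uPa at `reference_distance`.
#' @examples
#' source_level(83, measurement_distance = 0.1)  # 63 dB at 1 m
#' @export
source_level <- function(aspl, measurement_distance, reference_distance = 1) {
  if (measurement_distance <= 0 || reference_distance <= 0)
    stop("distances must be positive")
  aspl - 20 * log10(reference_distance / measurement_distance)
}

#' Summarise call levels by individual and call type
#'
#' Hierarchical level summary: per-individual means first, then an unweighted
#' population mean (and SD) of the individual means per call type — so
#' individuals recorded more often do not dominate — plus a Welch two-sample
#' t-test between the two call types on the individual means.
#'
#' @param measurements data.frame with columns `call_id`, `individual`,
#'   `call_type`, and one or more numeric level columns (e.g. `peak_level`,
#'   `rms_level`).
#' @param measures names of the level columns to summarise.
#' @return list with `individual_means` (data.frame), `population` (per-type
#'   mean/SD/max per measure) and `comparison` (Welch test per measure, or
#'   `NULL` with a warning when a type has fewer than 2 individuals).
#' @export
summarize_levels <- function(measurements,
                             measures = c("peak_level", "rms_level")) {
  need <- c("individual", "call_type", measures)
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ind <- stats::aggregate(measurements[measures],
                          by = list(individual = measurements$individual,
                                    call_type = measurements$call_type),
                          FUN = mean)
  pop <- do.call(rbind, lapply(split(ind, ind$call_type), function(g) {
    data.frame(call_type = g$call_type[1L],
               measure = measures,
               mean = vapply(measures, function(m) mean(g[[m]]), numeric(1)),
               sd = vapply(measures, function(m) stats::sd(g[[m]]), numeric(1)),
               max = vapply(measures, function(m) max(g[[m]]), numeric(1)),
               n_individuals = nrow(g), row.names = NULL)
  }))
  rownames(pop) <- NULL
  types <- unique(ind$call_type)
  comparison <- NULL
  if (length(types) == 2L &&
      all(table(ind$call_type) >= 2L)) {
    comparison <- lapply(measures, function(m) {
      tt <- stats::t.test(ind[[m]][ind$call_type == types[1L]],
                          ind[[m]][ind$call_type == types[2L]])
      data.frame(measure = m, statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_diff = unname(diff(rev(tt$estimate))))
    })
    comparison <- do.call(rbind, comparison)
  } else {
    warning("call-type comparison skipped: need 2 call types with >= 2 ",
            "individuals each")
  }
  list(individual_means = ind, population = pop, comparison = comparison)
}
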