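#' Log-spaced distance grid
#'
#' Builds the truncated log-spaced grid of modelling distances:
#' \code{floor(10^(k * log10(d_max/d_min) / (n_points - 1))) * d_min} for
#' k = 0 .. n_points - 1. With the defaults (10 points, 1-1000 m) this yields
#' exactly 1, 2, 4, 10, 21, 46, 100, 215, 464, 1000 m.
#'
#' @param n_points number of distances (>= 2).
#' @param d_min minimum distance in metres (>= 1, the spreading reference).
#' @param d_max maximum distance in metres (> d_min).
#' @return integer-valued numeric vector of distances in metres, class
#'   `distance_grid`.
#' @examples
#' distance_grid()
#' @export
distance_grid <- function(n_points = 10, d_min = 1, d_max = 1000) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (d_min < 1) stop("d_min must be >= 1 m")
  if (d_max <= d_min) stop("d_max must exceed d_min")
  k <- seq_len(n_points) - 1
  d <- floor(10^(k * log10(d_max / d_min) / (n_points - 1))) * d_min
  if (is.unsorted(d, strictly = TRUE))
    stop("degenerate grid: distances are not strictly increasing")
  structure(d, class = c("distance_grid", class(d)))
}

#' Propagation gain from spreading plus absorption
#'
#' Broadband level change, in dB, of a tone at `frequency` propagated from
#' `reference_distance` to `distance` under spherical spreading and
#' atmospheric absorption:
#' \code{gain = -20 log10(r/r0) - alpha(f) (r - r0)}.
#' Zero at the reference distance, strictly decreasing in distance, and
#' (for r > r0) decreasing in frequency — the low-pass action of the
#' atmosphere.
#'
#' @param frequency frequency in Hz (vectorised).
#' @param distance receiver distance in metres (>= `reference_distance`).
#' @param conditions a [meteo_conditions()].
#' @param reference_distance source reference distance in metres (default 1).
#' @return gain in dB (<= 0).
#' @export
propagation_gain <- function(frequency, distance, conditions,
                             reference_distance = 1) {
  if (reference_distance <= 0) stop("reference_distance must be positive")
  if (any(distance < reference_distance))
    stop("distance must be >= reference_distance (no back-propagation here; ",
         "see source_level() for the measurement-distance back-calculation)")
  alpha <- absorption_coefficient(frequency, conditions)
  -20 * log10(distance / reference_distance) -
    alpha * (distance - reference_distance)
}

#' Attenuate a waveform to a given distance
#'
#' Applies the frequency-dependent propagation gain to a calibrated waveform
#' by scaling the magnitude of each bin of a single whole-signal FFT
#' (zero phase change) and inverse-transforming. Sample count, rate and
#' calibration offset are preserved, so absolute levels of the output reflect
#' the attenuation.
#'
#' @param wave a [waveform()].
#' @param distance receiver distance in metres (>= `reference_distance`).
#' @param conditions a [meteo_conditions()].
#' @param reference_distance source reference distance in metres (default 1).
#' @return the attenuated [waveform()].
#' @export
attenuate_waveform <- function(wave, distance, conditions,
                               reference_distance = 1) {
  stopifnot(inherits(wave, "waveform"))
  if (distance < reference_distance)
    stop("distance must be >= reference_distance")
  if (is_silent(wave)) {
    warning("silent input returned unchanged")
    return(wave)
  }
  n <- length(wave$samples)
  spec <- stats::fft(wave$samples)
  # bin frequencies, folded so negative-frequency bins share the gain
  f <- seq_len(n) - 1
  f <- ifelse(f > n / 2, n - f, f) * wave$sample_rate / n
  gain <- propagation_gain(f, distance, conditions, reference_distance)
  out <- Re(stats::fft(spec * 10^(gain / 20), inverse = TRUE)) / n
  waveform(out, wave$sample_rate, wave$calibration_offset,
           provenance = wave$provenance)
}

#' Propagate a batch of calls over months and distances
#'
#' Models every call under every month's mean conditions at every grid
#' distance, writing one output file per combination (WAV, float32) and
#' returning a manifest. The manifest has exactly
#' `n_calls * n_months * n_distances` rows; per-item failures are recorded in
#' the manifest `status` column rather than aborting the batch.
#'
#' @param calls list of [waveform()]s; names (or provenance) become call ids.
#' @param monthly_conditions named list of [meteo_conditions()].
#' @param grid a [distance_grid()] (or numeric distances).
#' @param output_dir directory for output WAVs; created if needed. `NULL`
#'   keeps the attenuated waveforms in memory (manifest column `wave`).
#' @param reference_distance source reference distance in metres.
#' @return data.frame manifest with columns `call_id`, `month`, `distance_m`,
#'   `path` (or `wave`), `broadband_gain_dB` (RMS level change), `status`.
#' @export
batch_propagate <- function(calls, monthly_conditions, grid,
                            output_dir = NULL, reference_distance = 1) {
  if (!length(calls)) stop("no calls supplied")
  if (!length(monthly_conditions)) stop("no monthly conditions supplied")
  if (!length(grid)) stop("empty distance grid")
  ids <- names(calls)
  if (is.null(ids))
    ids <- vapply(seq_along(calls), function(i) {
      p <- calls[[i]]$provenance
      if (nzchar(p)) p else sprintf("call%03d", i)
    }, character(1))
  months <- names(monthly_conditions)
  if (is.null(months)) months <- sprintf("month%d", seq_along(monthly_conditions))
  in_memory <- is.null(output_dir)
  if (!in_memory && !dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", output_dir)
  rows <- vector("list", length(calls) * length(months) * length(grid))
  waves <- if (in_memory) vector("list", length(rows))
  i <- 0L
  for (ci in seq_along(calls)) for (mi in seq_along(months)) for (d in grid) {
    i <- i + 1L
    rec <- list(call_id = ids[ci], month = months[mi], distance_m = d,
                path = NA_character_, broadband_gain_dB = NA_real_,
                status = "ok")
    res <- tryCatch({
      att <- attenuate_waveform(calls[[ci]], d, monthly_conditions[[mi]],
                                reference_distance)
      rec$broadband_gain_dB <-
        20 * log10(wave_rms(att) / wave_rms(calls[[ci]]))
      if (in_memory) {
        waves[[i]] <- att
      } else {
        rec$path <- file.path(output_dir,
                              sprintf("%s_%s_%04dm.wav", ids[ci], months[mi],
                                      as.integer(round(d))))
        write_wav(att, rec$path)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) rec$status <- paste("error:", res)
    rows[[i]] <- rec
  }
  manifest <- do.call(rbind, lapply(rows, as.data.frame))
  if (in_memory) manifest$wave <- waves
  class(manifest) <- c("propagation_manifest", "data.frame")
  manifest
}

#' Write a propagation manifest
#'
#' @param manifest a manifest from [batch_propagate()].
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  d <- as.data.frame(manifest)
  d$wave <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(d, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}
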