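#' Pipeline run configuration
#'
#' One structured configuration object holding every constant of the
#' analysis protocol as a named, documented default: 10 log-spaced distances
#' over 1-1000 m referenced at 1 m, four breeding-season months, a 0.1 m
#' nominal recording distance, the 60 dB / 500-2000 Hz / 5 ms analysis
#' settings, the 200-entry cleaning threshold and 1000 permutations. A
#' configuration serialises to YAML-free plain JSON via [write_run_config()]
#' and reloads to an equal object.
#'
#' @param mode `"synthetic"` (generate calls with known ground truth) or
#'   `"real-data"` (read WAVs and a calibration tone from disk).
#' @param output_dir directory for stage outputs.
#' @param calls_dir,meteo_file,calibration_tone,calibration_spl real-data
#'   inputs: call WAV directory, station CSV, reference tone WAV and its
#'   meter reading in dB re 20 uPa.
#' @param measurement_distance recording distance in metres (default 0.1).
#' @param months month labels modelled (default May-August).
#' @param grid_n,grid_min,grid_max distance-grid parameters (default
#'   10 points, 1-1000 m).
#' @param n_individuals,calls_per_individual,call_type synthetic-mode
#'   generator sizes (defaults 11 individuals, 20 calls, `"classic"`).
#' @param settings an [analysis_settings()].
#' @param min_entries cleaning threshold (default 200 rows per individual).
#' @param n_permutations pDFA permutations (default 1000).
#' @param split training fraction for the SVM stage.
#' @param seed master seed; every stochastic stage derives its own logged
#'   seed from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real-data"),
                       output_dir = tempfile("aukprop_run_"),
                       calls_dir = NULL, meteo_file = NULL,
                       calibration_tone = NULL, calibration_spl = NULL,
                       measurement_distance = 0.1,
                       months = c("May", "June", "July", "August"),
                       grid_n = 10, grid_min = 1, grid_max = 1000,
                       n_individuals = 11, calls_per_individual = 20,
                       call_type = "classic",
                       settings = analysis_settings(),
                       min_entries = 200, n_permutations = 1000,
                       split = 0.8, seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, output_dir = output_dir, calls_dir = calls_dir,
              meteo_file = meteo_file, calibration_tone = calibration_tone,
              calibration_spl = calibration_spl,
              measurement_distance = measurement_distance, months = months,
              grid_n = grid_n, grid_min = grid_min, grid_max = grid_max,
              n_individuals = n_individuals,
              calls_per_individual = calls_per_individual,
              call_type = call_type, settings = unclass(settings),
              min_entries = min_entries, n_permutations = n_permutations,
              split = split, seed = seed)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$mode == "real-data") {
    for (f in c("calls_dir", "meteo_file", "calibration_tone")) {
      if (is.null(cfg[[f]]))
        stop("real-data mode requires config field '", f, "'")
      if (!file.exists(cfg[[f]]))
        stop("config field '", f, "' points to a missing path: ", cfg[[f]])
    }
    if (is.null(cfg$calibration_spl))
      stop("real-data mode requires config field 'calibration_spl'")
  }
  if (is.null(cfg$seed)) stop("an explicit seed is required")
  invisible(cfg)
}

#' Serialise / reload a run configuration
#'
#' @param cfg a [run_config()].
#' @param path JSON path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reloaded `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$settings <- do.call(analysis_settings, as.list(cfg$settings))
  cfg$settings <- unclass(cfg$settings)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

# drop later members of (near-)perfectly correlated feature pairs, which
# would make the correlation matrix singular for KMO/PCA
drop_collinear <- function(x, limit = 0.9999) {
  r <- abs(stats::cor(as.matrix(x)))
  keep <- rep(TRUE, ncol(x))
  for (j in seq_len(ncol(x))[-1L])
    if (any(r[j, seq_len(j - 1L)][keep[seq_len(j - 1L)]] > limit))
      keep[j] <- FALSE
  names(x)[keep]
}

log_stage <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' End-to-end reproducible run: acquire calls (synthesis or disk),
#' propagate each call to every grid distance under every month's
#' conditions, extract the 15-parameter feature set from every modelled
#' call, clean, then compute the level summary, per-distance and pooled
#' nested pDFA, per-distance Beecher's Hs, and the supervised-embedding SVM
#' accuracy profile with its distance trend. Stage outputs are written to
#' `cfg$output_dir` as CSV/JSON; every stochastic stage derives and logs
#' its seed from the master seed, and a rerun with the same configuration
#' reproduces the feature table bit for bit.
#'
#' @param cfg a [run_config()].
#' @return list of class `pipeline_result`: `features` (the modelled-call
#'   feature table), `levels`, `pdfa_by_distance`, `pdfa_pooled`,
#'   `hs_by_distance`, `accuracy`, `manifest_path`, `config`.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  settings <- do.call(analysis_settings, as.list(cfg$settings))
  grid <- distance_grid(cfg$grid_n, cfg$grid_min, cfg$grid_max)

  # -- stage 1: calls -------------------------------------------------------
  if (cfg$mode == "synthetic") {
    log_stage(log_path, "stage calls: synthesizing %d individuals x %d calls",
              cfg$n_individuals, cfg$calls_per_individual)
    inds <- make_individuals(cfg$n_individuals, seed = cfg$seed)
    calls <- list()
    truth <- list()
    for (i in seq_along(inds)) for (j in seq_len(cfg$calls_per_individual)) {
      w <- synthesize_call(inds[[i]], cfg$call_type,
                           seed = cfg$seed + 1000L * i + j)
      calls[[w$provenance]] <- w
      truth[[w$provenance]] <- inds[[i]]$id
    }
    individual_of <- unlist(truth)
    meteo <- lapply(stats::setNames(cfg$months, cfg$months), synth_meteo,
                    seed = cfg$seed)
  } else {
    paths <- list.files(cfg$calls_dir, pattern = "\\.wav$", full.names = TRUE,
                        ignore.case = TRUE)
    if (!length(paths)) stop("stage calls: no WAV files in ", cfg$calls_dir)
    log_stage(log_path, "stage calls: reading %d files", length(paths))
    tone <- read_wav(cfg$calibration_tone)
    offset <- calibration_offset(tone, cfg$calibration_spl)
    calls <- lapply(paths, function(p) calibrate(read_wav(p), offset))
    names(calls) <- sub("\\.wav$", "", basename(paths), ignore.case = TRUE)
    # individual id: leading token of the file name (id_whatever.wav)
    individual_of <- stats::setNames(sub("[_.].*$", "", names(calls)),
                                     names(calls))
    meteo <- monthly_mean_conditions(read_meteo_csv(cfg$meteo_file),
                                     cfg$months)
  }

  # -- stage 2: levels ------------------------------------------------------
  log_stage(log_path, "stage levels: %d calls", length(calls))
  lv <- data.frame(call_id = names(calls),
                   individual = unname(individual_of[names(calls)]),
                   call_type = cfg$call_type %||% "call",
                   peak_level = vapply(calls, function(w)
                     source_level(as.numeric(aspl_peak(w)),
                                  cfg$measurement_distance), numeric(1)),
                   rms_level = vapply(calls, function(w)
                     source_level(as.numeric(aspl_rms95(w)),
                                  cfg$measurement_distance), numeric(1)),
                   row.names = NULL)
  utils::write.csv(lv, file.path(cfg$output_dir, "levels.csv"),
                   row.names = FALSE)

  # -- stage 3: propagate + extract (streaming) -----------------------------
  log_stage(log_path,
            "stage propagate+features: %d calls x %d months x %d distances",
            length(calls), length(meteo), length(grid))
  feats <- vector("list", length(calls) * length(meteo) * length(grid))
  i <- 0L
  for (id in names(calls)) for (m in names(meteo)) for (d in grid) {
    i <- i + 1L
    att <- attenuate_waveform(calls[[id]], d, meteo[[m]])
    f <- extract_features(att, settings)
    feats[[i]] <- cbind(data.frame(call_id = sprintf("%s_%s_%04dm", id, m,
                                                     as.integer(round(d))),
                                   individual = unname(individual_of[[id]]),
                                   call_type = cfg$call_type %||% "call",
                                   month = m, distance_m = d,
                                   source_file = id,
                                   stringsAsFactors = FALSE),
                        as.data.frame(f))
  }
  features <- do.call(rbind, feats)
  utils::write.csv(features, file.path(cfg$output_dir, "features.csv"),
                   row.names = FALSE)

  # -- stage 4: clean + reduce ---------------------------------------------
  cleaned <- clean_table(features, min_entries = cfg$min_entries)
  log_stage(log_path, "stage clean: %d of %d rows, %d individuals retained",
            nrow(cleaned), nrow(features), length(unique(cleaned$individual)))
  fc <- feature_columns(cleaned)
  fc <- fc[vapply(cleaned[fc], function(v) stats::sd(v) > 0, logical(1))]
  fc <- drop_collinear(cleaned[fc])
  adequacy <- kmo(cleaned[fc])
  pca <- pca_kaiser(cleaned[fc])
  scores <- pca$scores

  # -- stage 5: pDFA --------------------------------------------------------
  log_stage(log_path, "stage pdfa: %d permutations", cfg$n_permutations)
  by_dist <- lapply(sort(unique(cleaned$distance_m)), function(d) {
    sel <- cleaned$distance_m == d
    r <- nested_pdfa(scores[sel, pca$retained, drop = FALSE],
                     cleaned$individual[sel], cleaned$source_file[sel],
                     n_permutations = cfg$n_permutations,
                     seed = cfg$seed + as.integer(d))
    data.frame(distance_m = d, observed_correct_pct = r$observed_correct_pct,
               chance_correct_pct = r$chance_correct_pct,
               p_correct = r$p_correct,
               observed_cross_pct = r$observed_cross_pct,
               chance_cross_pct = r$chance_cross_pct, p_cross = r$p_cross,
               relative_cross = r$relative_cross)
  })
  pdfa_by_distance <- do.call(rbind, by_dist)
  pdfa_pooled <- nested_pdfa(scores[, pca$retained, drop = FALSE],
                             cleaned$individual, cleaned$source_file,
                             n_permutations = cfg$n_permutations,
                             seed = cfg$seed + 7919L)
  utils::write.csv(pdfa_by_distance,
                   file.path(cfg$output_dir, "pdfa_by_distance.csv"),
                   row.names = FALSE)

  # -- stage 6: Beecher's Hs per distance -----------------------------------
  log_stage(log_path, "stage hs")
  # Hs on the Kaiser-retained components, like the discriminant stage:
  # summing HS_i across components assumes each carries independent
  # information, and the discarded small components are exactly where
  # distance-conditional collinearity (features collapsing onto the
  # fundamental at extreme attenuation) would double-count one cue
  hs_rows <- lapply(sort(unique(cleaned$distance_m)), function(d) {
    sel <- cleaned$distance_m == d
    h <- beechers_hs(scores[sel, pca$retained, drop = FALSE],
                     cleaned$individual[sel])
    data.frame(distance_m = d, hs_significant = h$hs_significant,
               hs_all = h$hs_all, meaning = h$n_distinguishable)
  })
  hs_by_distance <- do.call(rbind, hs_rows)
  utils::write.csv(hs_by_distance,
                   file.path(cfg$output_dir, "hs_by_distance.csv"),
                   row.names = FALSE)

  # -- stage 7: embedding + SVM --------------------------------------------
  log_stage(log_path, "stage classify")
  accuracy <- classify_by_distance(
    cleaned, embedding_config(n_neighbors = max(2, min(200, nrow(cleaned) %/% 20)),
                              seed = cfg$seed),
    split = cfg$split)
  utils::write.csv(accuracy$table,
                   file.path(cfg$output_dir, "accuracy_by_distance.csv"),
                   row.names = FALSE)

  summary_json <- list(
    kmo_overall = adequacy$overall,
    pca_retained = pca$retained_count,
    pdfa_pooled = unclass(pdfa_pooled)[c(
      "observed_correct_pct", "chance_correct_pct", "p_correct",
      "observed_cross_pct", "chance_cross_pct", "p_cross",
      "relative_cross")],
    accuracy_trend = list(slope = accuracy$trend$slope,
                          p_value = accuracy$trend$p_value),
    seed = cfg$seed)
  jsonlite::write_json(summary_json,
                       file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(log_path, "done")

  structure(list(features = features, cleaned = cleaned, levels = lv,
                 kmo = adequacy, pca = pca,
                 pdfa_by_distance = pdfa_by_distance,
                 pdfa_pooled = pdfa_pooled,
                 hs_by_distance = hs_by_distance, accuracy = accuracy,
                 output_dir = cfg$output_dir, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("aukprop pipeline result\n")
  cat(sprintf("  %d modelled calls (%d after cleaning), %d individuals\n",
              nrow(x$features), nrow(x$cleaned),
              length(unique(x$cleaned$individual))))
  cat(sprintf("  KMO %.3f, %d PCs retained\n", x$kmo$overall,
              x$pca$retained_count))
  print(x$pdfa_pooled)
  cat("Hs by distance:\n")
  print(x$hs_by_distance, row.names = FALSE)
  print(x$accuracy)
  invisible(x)
}
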