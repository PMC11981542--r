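#' Supervised-embedding configuration
#'
#' Settings for the 2-D supervised embedding step preceding the
#' support-vector classifier. `n_neighbors` and `min_dist` parametrise
#' neighbourhood-graph embedding backends; the discriminant backend shipped
#' with this package (see [supervised_embed()]) is deterministic and does
#' not consume them, but they are kept in the configuration so embedding
#' backends can be swapped without changing call sites.
#'
#' @param n_neighbors neighbourhood size (>= 2; conventionally 500 for long
#'   compound calls, 200 for short single-syllable calls).
#' @param min_dist minimum embedding distance in (0, 1]; default 0.5.
#' @param metric distance metric name; default `"euclidean"`.
#' @param seed integer seed.
#' @return list of class `embedding_config`.
#' @export
embedding_config <- function(n_neighbors = 200, min_dist = 0.5,
                             metric = "euclidean", seed = 1) {
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  if (min_dist <= 0 || min_dist > 1) stop("min_dist must be in (0, 1]")
  structure(list(n_neighbors = n_neighbors, min_dist = min_dist,
                 metric = metric, seed = seed),
            class = "embedding_config")
}

#' Supervised 2-D embedding of a feature table
#'
#' Maps labelled feature rows to two dimensions for visualisation and
#' downstream maximum-margin classification. The backend is a Fisher
#' discriminant Sammon mapping: standardised features are projected onto
#' all linear discriminant axes of the class labels (the supervision step),
#' and that discriminant configuration is laid out in 2-D by Sammon's
#' nonlinear mapping, which preserves between-cluster structure that a
#' linear truncation to two axes would collapse. With two classes (a single
#' discriminant axis) the second coordinate is the leading residual
#' principal component instead.
#'
#' The mapping is deterministic for a fixed `config$seed` (the seed feeds
#' only the infinitesimal jitter that separates exactly duplicated rows,
#' which Sammon's stress cannot handle), and yields finite coordinates for
#' degenerate inputs. Cost grows with the squared row count; intended for
#' per-distance subsets of a few thousand rows.
#'
#' @param features numeric matrix/data.frame of predictors.
#' @param labels class labels, one per row.
#' @param config an [embedding_config()].
#' @return n x 2 numeric matrix of embedding coordinates.
#' @export
supervised_embed <- function(features, labels, config = embedding_config()) {
  x <- as.matrix(features)
  labels <- factor(labels)
  if (nrow(x) <= config$n_neighbors)
    stop("n_neighbors (", config$n_neighbors, ") must be smaller than the ",
         "number of rows (", nrow(x), ")")
  keep <- apply(x, 2L, stats::sd) > 1e-12
  if (!any(keep)) stop("all predictors are constant")
  z <- scale(x[, keep, drop = FALSE])
  # collinearity is harmless for a pure projection; silence lda's warning
  fit <- withCallingHandlers(
    MASS::lda(z, grouping = labels, tol = 1e-8),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ld <- stats::predict(fit, z)$x
  if (ncol(ld) == 1L) {
    # two classes give one discriminant axis: pad with the leading residual PC
    resid <- z - tcrossprod(ld[, 1L] / sum(ld[, 1L]^2),
                            crossprod(z, ld[, 1L]))
    pc1 <- stats::prcomp(resid, center = FALSE)$x[, 1L]
    return(unname(cbind(ld[, 1L], pc1)))
  }
  if (ncol(ld) == 2L) return(unname(ld))
  # nonlinear 2-D layout of the full discriminant configuration
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  ldj <- ld + matrix(stats::rnorm(length(ld), 0, 1e-6), nrow(ld))
  sm <- MASS::sammon(stats::dist(ldj), k = 2L, trace = FALSE, niter = 200L)
  unname(sm$points)
}

#' Class-weighted maximum-margin classification accuracy
#'
#' Stratified 80:20 train/test split of the embedded coordinates, followed
#' by a support-vector classifier with class weights inversely proportional
#' to class frequency (so rarely-recorded individuals are not swamped by
#' well-sampled ones); returns held-out accuracy in percent.
#'
#' @param coords numeric matrix of (embedding) coordinates.
#' @param labels class labels, one per row; every class needs >= 2 rows.
#' @param split training fraction (default 0.8).
#' @param seed integer seed for the stratified split.
#' @return accuracy in percent, with attribute `n_test`.
#' @export
weighted_accuracy <- function(coords, labels, split = 0.8, seed = 1) {
  x <- as.matrix(coords)
  y <- factor(labels)
  small <- names(which(table(y) < 2L))
  if (length(small))
    stop("class(es) with fewer than 2 rows: ", paste(small, collapse = ", "))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  tr <- logical(nrow(x))
  for (lv in levels(y)) {
    rows <- which(y == lv)
    n_tr <- max(1L, min(length(rows) - 1L, round(split * length(rows))))
    tr[sample(rows, n_tr)] <- TRUE
  }
  freq <- table(y[tr])
  w <- as.numeric(sum(freq) / (length(freq) * freq))
  names(w) <- names(freq)
  fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], class.weights = w)
  pred <- stats::predict(fit, x[!tr, , drop = FALSE])
  acc <- 100 * mean(pred == y[!tr])
  attr(acc, "n_test") <- sum(!tr)
  acc
}

#' Trend of classification accuracy over distance
#'
#' Ordinary least squares of accuracy (percent) on log10(distance), with a
#' two-sided test of the slope — the test of whether classification
#' performance degrades as the modelled signal travels. A constant accuracy
#' profile returns slope 0 with p = 1 by convention.
#'
#' @param table data.frame with columns `distance_m` and `accuracy_pct`
#'   (>= 3 distances).
#' @return list of class `accuracy_trend`: `slope` (percent per decade of
#'   distance), `p_value`, `fit` (the `lm` object or `NULL`).
#' @export
accuracy_trend <- function(table) {
  stopifnot(all(c("distance_m", "accuracy_pct") %in% names(table)))
  if (nrow(table) < 3L) stop("need >= 3 distances")
  if (stats::var(table$accuracy_pct) == 0)
    return(structure(list(slope = 0, p_value = 1, fit = NULL),
                     class = "accuracy_trend"))
  fit <- stats::lm(accuracy_pct ~ log10(distance_m), data = table)
  s <- summary(fit)$coefficients
  structure(list(slope = unname(s[2L, 1L]), p_value = unname(s[2L, 4L]),
                 fit = fit),
            class = "accuracy_trend")
}

#' @export
print.accuracy_trend <- function(x, ...) {
  cat(sprintf("accuracy ~ log10(distance): slope %.3f %%/decade, p = %.3g\n",
              x$slope, x$p_value))
  invisible(x)
}

#' Per-distance embedding + classification table
#'
#' For each modelled distance, embeds that distance's calls with
#' [supervised_embed()], measures held-out accuracy with
#' [weighted_accuracy()], and tests the accuracy-vs-distance trend.
#'
#' @param features data.frame with `individual`, `distance_m` and feature
#'   columns (see [clean_table()]).
#' @param config an [embedding_config()]; `n_neighbors` is clipped to the
#'   per-distance subset size when necessary.
#' @param split training fraction for [weighted_accuracy()].
#' @return list of class `accuracy_by_distance`: `table` (distance,
#'   accuracy, n_test) and `trend`.
#' @export
classify_by_distance <- function(features, config = embedding_config(),
                                 split = 0.8) {
  stopifnot(all(c("individual", "distance_m") %in% names(features)))
  fc <- feature_columns(features)
  dists <- sort(unique(features$distance_m))
  rows <- lapply(dists, function(d) {
    sub <- features[features$distance_m == d, , drop = FALSE]
    cfg <- config
    cfg$n_neighbors <- min(cfg$n_neighbors, nrow(sub) - 1L)
    coords <- supervised_embed(sub[fc], sub$individual, cfg)
    acc <- weighted_accuracy(coords, sub$individual, split = split,
                             seed = config$seed)
    data.frame(distance_m = d, accuracy_pct = as.numeric(acc),
               n_test = attr(acc, "n_test"))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 trend = if (nrow(tab) >= 3L) accuracy_trend(tab)),
            class = "accuracy_by_distance")
}

#' @export
print.accuracy_by_distance <- function(x, ...) {
  cat("SVM accuracy on supervised-embedded calls, per distance:\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$trend)) print(x$trend)
  invisible(x)
}
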