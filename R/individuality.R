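# identifier columns recognised in a feature table; everything else numeric
# is treated as a feature variable
ID_COLUMNS <- c("call_id", "individual", "call_type", "month", "distance_m",
                "source_file")

feature_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          ID_COLUMNS)
}

#' Clean a feature table
#'
#' Applies the two dataset-cleaning rules used throughout the pipeline:
#' rows with any missing feature value are removed (listwise deletion), and
#' individuals with fewer than `min_entries` remaining rows are dropped
#' entirely. With the default threshold of 200 entries, an individual must
#' retain at least five calls propagated four times to ten distances.
#'
#' @param raw data.frame with an `individual` column and numeric feature
#'   columns (identifier columns `call_id`, `call_type`, `month`,
#'   `distance_m`, `source_file` are recognised and preserved).
#' @param min_entries minimum rows per retained individual (default 200).
#' @return the cleaned data.frame.
#' @export
clean_table <- function(raw, min_entries = 200) {
  if (!"individual" %in% names(raw)) stop("table lacks an 'individual' column")
  fc <- feature_columns(raw)
  if (!length(fc)) stop("table has no feature columns")
  keep <- stats::complete.cases(raw[fc])
  out <- raw[keep, , drop = FALSE]
  counts <- table(out$individual)
  out <- out[out$individual %in% names(counts)[counts >= min_entries], ,
             drop = FALSE]
  if (!nrow(out)) stop("no individuals survive cleaning")
  rownames(out) <- NULL
  out
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares observed pairwise correlations with anti-image partial
#' correlations: \code{KMO = sum(r^2) / (sum(r^2) + sum(q^2))} over
#' off-diagonal elements, where the partials q come from the inverted
#' correlation matrix. Values near 1 indicate data well suited to factor
#' decomposition; independent variables give values near 0.5.
#'
#' @param x numeric matrix or data.frame of variables (>= 2 columns).
#' @return list of class `kmo`: `overall` in \[0, 1\] and `per_variable`.
#' @export
kmo <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 variables")
  R <- stats::cor(x)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; drop collinear variables ",
         "before computing KMO"))
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)  # anti-image partial correlations
  diag(R) <- 0
  diag(Q) <- 0
  r2 <- colSums(R^2)
  q2 <- colSums(Q^2)
  structure(list(overall = sum(r2) / (sum(r2) + sum(q2)),
                 per_variable = stats::setNames(r2 / (r2 + q2), colnames(x))),
            class = "kmo")
}

#' @export
print.kmo <- function(x, ...) {
  cat(sprintf("Kaiser-Meyer-Olkin adequacy: overall %.3f\n", x$overall))
  print(round(x$per_variable, 3))
  invisible(x)
}

#' Principal components with Kaiser retention
#'
#' Standardises the variables, eigen-decomposes their correlation matrix and
#' flags the components with eigenvalue > 1 (the Kaiser criterion) for use
#' as reduced inputs to the discriminant and information analyses. All
#' component scores are kept in the object; the Kaiser subset is a flag,
#' not a truncation.
#'
#' @param x numeric matrix or data.frame of cleaned features.
#' @return list of class `pca_kaiser`: `eigenvalues` (descending),
#'   `loadings`, `scores`, `retained` (logical), `retained_count`, `center`,
#'   `scale`.
#' @export
pca_kaiser <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  ev <- e$values
  if (max(ev) < 1.1)
    warning("all eigenvalues near 1: Kaiser retention is unstable ",
            "(variables appear mutually uncorrelated)")
  retained <- ev > 1
  if (!any(retained)) retained[1L] <- TRUE
  scores <- z %*% e$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  colnames(e$vectors) <- colnames(scores)
  rownames(e$vectors) <- colnames(x)
  structure(list(eigenvalues = ev, loadings = e$vectors, scores = scores,
                 retained = retained, retained_count = sum(retained),
                 center = attr(z, "scaled:center"),
                 scale = attr(z, "scaled:scale")),
            class = "pca_kaiser")
}

#' @export
print.pca_kaiser <- function(x, ...) {
  cat(sprintf("PCA on the correlation matrix: %d variables, %d components ",
              nrow(x$loadings), length(x$eigenvalues)),
      sprintf("with eigenvalue > 1 retained: %d\n", x$retained_count))
  cat("eigenvalues:", paste(round(x$eigenvalues, 3), collapse = " "), "\n")
  invisible(x)
}

# one DFA evaluation: balanced training selection over control groups,
# resubstitution accuracy on the training rows, cross accuracy on the rest
dfa_once <- function(scores, ind_of_group, row_group, n_train) {
  groups <- names(ind_of_group)
  train_groups <- unlist(lapply(split(groups, ind_of_group),
                                function(g) sample(g, n_train)))
  tr <- row_group %in% train_groups
  ind_rows <- ind_of_group[row_group]
  fit <- withCallingHandlers(
    MASS::lda(scores[tr, , drop = FALSE], grouping = factor(ind_rows[tr])),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pr_tr <- stats::predict(fit, scores[tr, , drop = FALSE])$class
  pr_cv <- stats::predict(fit, scores[!tr, , drop = FALSE])$class
  c(correct = 100 * mean(pr_tr == ind_rows[tr]),
    cross = 100 * mean(pr_cv == ind_rows[!tr]))
}

#' Nested permuted discriminant function analysis
#'
#' Linear discriminant classification of calls to individuals whose
#' significance is assessed by restricted permutations that respect the
#' nested structure of the data: rows belonging to one control-factor group
#' (e.g. all month-variants of one source recording) always move together,
#' correcting for multiple sampling of the same call.
#'
#' For the observed statistic, a balanced random selection of
#' `floor(train_fraction * min groups per individual)` control groups per
#' individual forms the training set; discriminant functions are fitted on
#' those rows, classification accuracy is measured on the training rows
#' (correct) and on the held-out rows (cross-classification). Permutations
#' reassign individual labels at the group level, preserving each
#' individual's group count, and recompute both statistics; the chance level
#' is their permutation mean and p-values use the add-one estimator
#' \code{(1 + #permuted >= observed) / (1 + n_permutations)}.
#'
#' @param scores numeric matrix of predictor scores (e.g. PC scores).
#' @param individual factor/character of individual labels, one per row.
#' @param control factor/character control-factor labels; every control
#'   group must lie wholly within one individual.
#' @param n_permutations number of permutations (default 1000).
#' @param seed integer seed for the permutation stream (required: results
#'   ship with their seed).
#' @param train_fraction fraction of each individual's groups used for
#'   training (default 2/3).
#' @return object of class `pdfa`: observed/chance/p for correct and
#'   cross-classification, `relative_cross`, `n_permutations`, `seed`,
#'   `n_train_groups`.
#' @export
nested_pdfa <- function(scores, individual, control, n_permutations = 1000,
                        seed, train_fraction = 2 / 3) {
  if (missing(seed)) stop("a permutation seed is required")
  scores <- as.matrix(scores)
  individual <- as.character(individual)
  control <- as.character(control)
  stopifnot(nrow(scores) == length(individual),
            length(individual) == length(control))
  if (length(unique(individual)) < 2L) stop("need >= 2 individuals")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  map <- unique(data.frame(control = control, individual = individual,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(map$control))
    stop("control group(s) span multiple individuals: ",
         paste(unique(map$control[duplicated(map$control)]), collapse = ", "))
  ind_of_group <- stats::setNames(map$individual, map$control)
  g_per_ind <- table(map$individual)
  n_train <- floor(train_fraction * min(g_per_ind))
  if (n_train < 1 || n_train >= min(g_per_ind))
    stop("too few control groups for a balanced split; limiting individual: ",
         names(g_per_ind)[which.min(g_per_ind)])
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  obs <- dfa_once(scores, ind_of_group, control, n_train)
  perm <- matrix(NA_real_, n_permutations, 2L,
                 dimnames = list(NULL, c("correct", "cross")))
  for (b in seq_len(n_permutations)) {
    shuffled <- stats::setNames(sample(unname(ind_of_group)), names(ind_of_group))
    perm[b, ] <- dfa_once(scores, shuffled, control, n_train)
  }
  structure(list(
    observed_correct_pct = unname(obs["correct"]),
    chance_correct_pct = mean(perm[, "correct"]),
    p_correct = (1 + sum(perm[, "correct"] >= obs["correct"])) /
      (1 + n_permutations),
    observed_cross_pct = unname(obs["cross"]),
    chance_cross_pct = mean(perm[, "cross"]),
    p_cross = (1 + sum(perm[, "cross"] >= obs["cross"])) /
      (1 + n_permutations),
    relative_cross = unname(obs["cross"]) / mean(perm[, "cross"]),
    n_permutations = n_permutations, seed = seed,
    n_train_groups = n_train),
    class = "pdfa")
}

#' @export
print.pdfa <- function(x, ...) {
  cat("Nested permuted DFA (", x$n_permutations, " permutations, seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  correctly classified: %.2f %% (chance %.2f %%, p = %.4g)\n",
              x$observed_correct_pct, x$chance_correct_pct, x$p_correct))
  cat(sprintf("  cross-classified:     %.2f %% (chance %.2f %%, p = %.4g, relative %.2f)\n",
              x$observed_cross_pct, x$chance_cross_pct, x$p_cross,
              x$relative_cross))
  invisible(x)
}

#' Beecher's information statistic
#'
#' Total individual-identity information carried by a set of variables, in
#' bits. For each variable a one-way ANOVA across individuals yields F; its
#' identity information is \code{HS_i = log2 sqrt((F + n - 1) / n)} with n
#' the number of observations per individual (harmonic mean when
#' unbalanced), floored at 0. Under the balanced one-way model the
#' expectation of HS_i is \code{0.5 log2(1 + s2_between/s2_within)}.
#' `hs_all` sums over all variables; `hs_significant` over the variables
#' whose ANOVA p < `alpha` (raw, unadjusted, following the convention of
#' the statistic). Summing across variables assumes they carry independent
#' information, which is why the statistic is normally applied to
#' orthogonal PC scores.
#'
#' @param x numeric matrix/data.frame of variables (typically PC scores).
#' @param individual individual labels, one per row.
#' @param alpha significance gate for `hs_significant` (default 0.05).
#' @return object of class `beechers_hs`: `per_variable` data.frame
#'   (F, p, HS bits), `hs_all`, `hs_significant`, `n_distinguishable`
#'   (= round(2^hs_all)), `n_harmonic`.
#' @export
beechers_hs <- function(x, individual, alpha = 0.05) {
  x <- as.matrix(x)
  individual <- factor(individual)
  if (nlevels(individual) < 2L) stop("need >= 2 individuals")
  counts <- table(individual)
  if (any(counts < 2L)) stop("every individual needs >= 2 observations")
  n_h <- length(counts) / sum(1 / counts)  # harmonic mean group size
  per <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (stats::var(v) == 0) {
      warning("variable ", j, " is constant; its HS is set to 0")
      return(data.frame(F = NA_real_, p = NA_real_, HS = 0))
    }
    a <- stats::anova(stats::lm(v ~ individual))
    Fv <- a[["F value"]][1L]
    data.frame(F = Fv, p = a[["Pr(>F)"]][1L],
               HS = max(0, log2(sqrt((Fv + n_h - 1) / n_h))))
  })
  per <- do.call(rbind, per)
  rownames(per) <- colnames(x) %||% paste0("v", seq_len(ncol(x)))
  hs_all <- sum(per$HS)
  hs_sig <- sum(per$HS[!is.na(per$p) & per$p < alpha])
  structure(list(per_variable = per, hs_all = hs_all,
                 hs_significant = hs_sig,
                 n_distinguishable = distinguishable_individuals(hs_all),
                 n_harmonic = n_h),
            class = "beechers_hs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beechers_hs <- function(x, ...) {
  cat(sprintf("Beecher's Hs: %.2f bits (significant variables only: %.2f)\n",
              x$hs_all, x$hs_significant))
  cat(sprintf("  => up to ~%d individuals theoretically distinguishable\n",
              x$n_distinguishable))
  invisible(x)
}

#' Distinguishable individuals implied by an information content
#'
#' A signal carrying Hs bits of identity information can in principle
#' separate \code{2^Hs} individuals; the count is reported rounded to the
#' nearest integer, computed on the unrounded statistic.
#'
#' @param hs identity information in bits (>= 0).
#' @return integer count.
#' @examples
#' distinguishable_individuals(2.8)  # 7
#' distinguishable_individuals(3.6)  # 12
#' @export
distinguishable_individuals <- function(hs) {
  if (any(!is.finite(hs)) || any(hs < 0)) stop("hs must be >= 0")
  as.integer(round(2^hs))
}
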