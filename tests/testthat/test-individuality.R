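test_that("cleaning removes incomplete rows and under-sampled individuals", {
  tab <- simulate_feature_table(3, 210, 1, 1, n_variables = 2, seed = 2)
  tab$v1[5] <- NA
  # drop individual 3 to 199 complete rows: it must vanish
  tab <- tab[-(which(tab$individual == "ind03")[1:11]), ]
  out <- clean_table(tab, min_entries = 200)
  expect_false(any(is.na(out$v1)))
  expect_setequal(unique(out$individual), c("ind01", "ind02"))
  expect_equal(sum(out$individual == "ind01"), 209)  # 210 minus the NA row
  # boundary: exactly 200 entries are kept
  tab200 <- simulate_feature_table(2, 200, 1, 1, n_variables = 2, seed = 3)
  expect_setequal(unique(clean_table(tab200)$individual),
                  c("ind01", "ind02"))
  # an already-clean table passes through unchanged
  expect_equal(clean_table(out, min_entries = 200), out)
  expect_error(clean_table(tab200, min_entries = 1000), "survive")
})

test_that("KMO agrees with brute-force partial correlations", {
  # two blocks of mutually correlated variables
  set.seed(31)
  n <- 400
  fA <- rnorm(n); fB <- rnorm(n)
  x <- cbind(a1 = fA + 0.4 * rnorm(n), a2 = fA + 0.4 * rnorm(n),
             a3 = fA + 0.4 * rnorm(n), b1 = fB + 0.4 * rnorm(n),
             b2 = fB + 0.4 * rnorm(n))
  k <- kmo(x)
  expect_gt(k$overall, 0.6)
  expect_equal(k$overall, kmo_bruteforce(x), tolerance = 1e-10)
  expect_true(all(k$per_variable >= 0 & k$per_variable <= 1))
  # independent variables converge to 0.5
  set.seed(32)
  xi <- matrix(rnorm(6 * 4000), ncol = 6)
  expect_equal(kmo(xi)$overall, 0.5, tolerance = 0.05)
  # a duplicated variable makes the correlation matrix singular
  expect_error(kmo(cbind(x, dup = x[, 1])), "singular")
})

test_that("PCA with Kaiser retention matches an independent decomposition", {
  set.seed(41)
  n <- 300
  f1 <- rnorm(n)
  x <- cbind(f1 + 0.3 * rnorm(n), f1 + 0.3 * rnorm(n), rnorm(n), rnorm(n),
             rnorm(n))
  p <- pca_kaiser(x)
  # independent spectral route: prcomp uses SVD of the scaled data
  expect_equal(p$eigenvalues, unname(stats::prcomp(x, scale. = TRUE)$sdev^2),
               tolerance = 1e-8)
  expect_equal(sum(p$eigenvalues), ncol(x), tolerance = 1e-8)
  expect_gte(p$retained_count, 1)
  expect_true(all(p$eigenvalues[p$retained] > 1))
  # two perfectly correlated variables push the top eigenvalue to >= 2
  y <- cbind(x[, 1], x[, 1], rnorm(n), rnorm(n))
  expect_gte(suppressWarnings(pca_kaiser(y))$eigenvalues[1], 2 - 1e-6)
  expect_error(pca_kaiser(cbind(x, rep(1, n))), "zero-variance")
  # population-identity correlation: retention flagged as unstable
  set.seed(42)
  expect_warning(pca_kaiser(matrix(rnorm(5 * 5000), ncol = 5)), "unstable")
})

test_that("nested pDFA separates what is separable and validates nesting", {
  # perfectly separated clusters: perfect classification, minimal p
  tab <- simulate_feature_table(4, 24, 100, 0.01, n_variables = 2, seed = 5)
  r <- nested_pdfa(tab[, c("v1", "v2")], tab$individual, tab$source_file,
                   n_permutations = 99, seed = 7)
  expect_equal(r$observed_correct_pct, 100)
  expect_equal(r$observed_cross_pct, 100)
  expect_equal(r$p_correct, 1 / 100)
  expect_equal(r$p_cross, 1 / 100)
  expect_true(r$chance_correct_pct < 100)
  # control groups spanning individuals are rejected
  bad <- tab$source_file
  bad[1] <- tab$source_file[tab$individual == "ind02"][1]
  expect_error(nested_pdfa(tab[, c("v1", "v2")], tab$individual, bad,
                           n_permutations = 9, seed = 1), "span")
  expect_error(nested_pdfa(tab[, c("v1", "v2")], tab$individual,
                           tab$source_file, n_permutations = 9), "seed")
  # two few groups for a balanced split names the limiting individual
  tiny <- simulate_feature_table(2, 4, 1, 1, group_size = 4, seed = 6)
  expect_error(nested_pdfa(tiny[, "v1", drop = FALSE], tiny$individual,
                           tiny$source_file, n_permutations = 9, seed = 1),
               "limiting individual")
})

test_that("pDFA chance level sits near 50% for two balanced individuals", {
  tab <- simulate_feature_table(2, 128, 0, 1, n_variables = 1,
                                group_size = 8, seed = 9)
  r <- nested_pdfa(tab[, "v1", drop = FALSE], tab$individual,
                   tab$source_file, n_permutations = 300, seed = 11)
  expect_equal(r$chance_correct_pct, 50, tolerance = 2)
  expect_equal(r$chance_cross_pct, 50, tolerance = 2)
})

test_that("Beecher's Hs follows its formula and additivity", {
  tab <- simulate_feature_table(6, 30, 3, 1, n_variables = 2, seed = 13)
  h <- beechers_hs(tab[, c("v1", "v2")], tab$individual)
  # formula check against a hand-computed ANOVA for v1
  a <- anova(lm(tab$v1 ~ factor(tab$individual)))
  expect_equal(h$per_variable$F[1], a[["F value"]][1])
  expect_equal(h$per_variable$HS[1],
               max(0, log2(sqrt((a[["F value"]][1] + 30 - 1) / 30))))
  # duplicating the variable set doubles hs_all
  h2 <- beechers_hs(tab[, c("v1", "v2", "v1", "v2")], tab$individual)
  expect_equal(h2$hs_all, 2 * h$hs_all, tolerance = 1e-9)
  expect_lte(h$hs_significant, h$hs_all)
  # a constant variable contributes 0 bits, with a warning
  tabc <- cbind(tab, v3 = 1)
  expect_warning(hc <- beechers_hs(tabc[, c("v1", "v3")], tabc$individual),
                 "constant")
  expect_equal(hc$per_variable$HS[2], 0)
  # no individual signal: F near 1 gives HS near 0
  null_tab <- simulate_feature_table(6, 100, 0, 1, n_variables = 8, seed = 14)
  hn <- beechers_hs(null_tab[, paste0("v", 1:8)], null_tab$individual)
  expect_lt(hn$hs_all / 8, 0.1)
})

test_that("hs_significant never exceeds hs_all across random tables", {
  for (seed in 1:6) {
    tab <- simulate_feature_table(4, 20, seed %% 3, 1, n_variables = 3,
                                  seed = seed)
    h <- beechers_hs(tab[, paste0("v", 1:3)], tab$individual)
    expect_lte(h$hs_significant, h$hs_all + 1e-12)
  }
})

test_that("information content translates to distinguishable individuals", {
  expect_equal(distinguishable_individuals(2.8), 7L)
  expect_equal(distinguishable_individuals(3.6), 12L)
  expect_equal(distinguishable_individuals(0), 1L)
  expect_error(distinguishable_individuals(-0.1), ">= 0")
})
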