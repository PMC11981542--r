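# Independently written single-file evaluation of the ISO 9613-1 closed
# forms: one monolithic vectorised expression, kept deliberately separate
# from the package's modular implementation so the two can cross-check.
iso9613_alpha_reference <- function(f, t_celsius, rh, p_kpa = 101.325) {
  T <- t_celsius + 273.15
  psat_over_pr <- 10^(-6.8346 * (273.16 / T)^1.261 + 4.6151)
  h <- rh * psat_over_pr / (p_kpa / 101.325)
  frO <- (p_kpa / 101.325) *
    (24 + 4.04e4 * h * (0.02 + h) / (0.391 + h))
  frN <- (p_kpa / 101.325) * (T / 293.15)^(-1 / 2) *
    (9 + 280 * h * exp(-4.170 * ((T / 293.15)^(-1 / 3) - 1)))
  8.686 * f^2 *
    (1.84e-11 * (p_kpa / 101.325)^(-1) * (T / 293.15)^(1 / 2) +
       (T / 293.15)^(-5 / 2) *
         (0.01275 * exp(-2239.1 / T) * (frO + f^2 / frO)^(-1) +
            0.1068 * exp(-3352 / T) * (frN + f^2 / frN)^(-1)))
}

# brute-force 95%-energy RMS: explicit cumulative scan with loops, the
# independent oracle for aspl_rms95()
rms95_bruteforce <- function(samples) {
  total <- sum(samples^2)
  acc <- 0
  i1 <- NA_integer_
  for (i in seq_along(samples)) {
    acc <- acc + samples[i]^2
    if (acc >= 0.025 * total) { i1 <- i; break }
  }
  acc <- 0
  i2 <- NA_integer_
  for (i in seq_along(samples)) {
    acc <- acc + samples[i]^2
    if (acc >= 0.975 * total) { i2 <- i; break }
  }
  sqrt(mean(samples[i1:i2]^2))
}

# partial correlations by explicit residualisation: regress each variable on
# all the others and correlate the residuals -- the independent route to the
# anti-image matrix used by kmo()
partial_cor_bruteforce <- function(x) {
  p <- ncol(x)
  q <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    others <- x[, -c(i, j), drop = FALSE]
    ri <- stats::residuals(stats::lm(x[, i] ~ others))
    rj <- stats::residuals(stats::lm(x[, j] ~ others))
    q[i, j] <- q[j, i] <- stats::cor(ri, rj)
  }
  q
}

kmo_bruteforce <- function(x) {
  r <- stats::cor(x)
  diag(r) <- 0
  q <- partial_cor_bruteforce(x)
  diag(q) <- 0
  sum(r^2) / (sum(r^2) + sum(q^2, na.rm = TRUE))
}
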