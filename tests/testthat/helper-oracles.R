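# Independent brute-force oracles, written as literal transcriptions of the
# defining formulas (plain loops, no shared code with the package).

# KPSS statistic: partial sums of regression residuals over a Bartlett
# long-run variance.
bf_kpss <- function(y, variant, nlags) {
  T_ <- length(y)
  if (variant == "level") {
    e <- y - mean(y)
  } else {
    fit <- stats::lm(y ~ seq_len(T_))
    e <- as.numeric(stats::residuals(fit))
  }
  s2 <- mean(e^2)
  if (nlags > 0) {
    for (l in seq_len(nlags)) {
      acc <- 0
      for (t in (l + 1):T_) acc <- acc + e[t] * e[t - l]
      s2 <- s2 + 2 * (1 - l / (nlags + 1)) * acc / T_
    }
  }
  S <- numeric(T_)
  run <- 0
  for (t in seq_len(T_)) {
    run <- run + e[t]
    S[t] <- run
  }
  sum(S^2) / (T_^2 * s2)
}

# Combined spectral dissimilarity: symmetric KL of the normalized spectra
# times (1 + mean absolute log deviation of the floored raw spectra).
bf_spectral_distance <- function(G, H, eps = 1e-12) {
  G2 <- pmax(G, eps * max(G))
  H2 <- pmax(H, eps * max(H))
  Gt <- G2 / sum(G2)
  Ht <- H2 / sum(H2)
  kl <- 0
  for (i in seq_along(Gt)) kl <- kl + (Gt[i] - Ht[i]) * log(Gt[i] / Ht[i])
  lsd <- 0
  for (i in seq_along(G2)) lsd <- lsd + abs(log(G2[i] / H2[i]))
  lsd <- lsd / length(G2)
  kl * (1 + lsd)
}

# Population variance of a divergence sequence.
bf_theta <- function(cvec) {
  m <- sum(cvec) / length(cvec)
  acc <- 0
  for (v in cvec) acc <- acc + (v - m)^2
  acc / length(cvec)
}

# Normalized per-puff MSE with mean-curve range normalization.
bf_puff_mse <- function(p, m) {
  acc <- 0
  for (i in seq_along(m)) acc <- acc + (p[i] - m[i])^2
  acc / (length(m) * (max(m) - min(m))^2)
}

# Discrete spectral moments.
bf_spectral_params <- function(f, P) {
  tot <- sum(P)
  fm <- sum(f * P) / tot
  list(f_mean = fm, f_max = f[which.max(P)],
       spec_sd = sqrt(sum((f - fm)^2 * P) / tot))
}

# Jaccard overlap of two half-open intervals.
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}
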