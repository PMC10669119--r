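test_that("hermite banks are orthonormal with the right node counts", {
  b1 <- hermite_bank(1, 65)
  expect_equal(sum(b1$windows[, 1]^2), 1, tolerance = 1e-12)
  expect_true(all(b1$windows[, 1] > 0))  # Gaussian: no sign change

  b <- hermite_bank(5, 257)
  G <- crossprod(b$windows)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  for (k in 1:5) {
    w <- b$windows[, k]
    w <- w[abs(w) > 1e-6 * max(abs(w))]
    expect_identical(sum(diff(sign(w)) != 0), k - 1L)
  }
  expect_error(hermite_bank(5, 256), "odd")
  expect_error(hermite_bank(5, 19), "4\\*K")
  expect_error(hermite_bank(0, 65), "K must")
})

test_that("multitaper spectrogram basics: zeros, K=1 reduction, short input", {
  bank <- hermite_bank(3, 33)
  z <- mt_spectrogram(numeric(500), bank)
  expect_equal(max(z$S), 0)
  expect_true(all(diff(z$tn) > 0))

  set.seed(2)
  x <- rnorm(400)
  b1 <- hermite_bank(1, 41)
  got <- mt_spectrogram(x, b1, stride = 20)
  # independent single-window spectrogram
  w <- b1$windows[, 1]
  for (i in seq_along(got$tn)) {
    c0 <- got$tn[i]
    seg <- x[(c0 - 20):(c0 + 20)] * w
    P <- Mod(stats::fft(seg))^2
    expect_equal(got$S[i, ], P[1:21], tolerance = 1e-12)
  }

  expect_error(mt_spectrogram(rnorm(30), bank), "shorter")
})

test_that("time-marginalized multitaper spectrum of white noise is flat", {
  set.seed(6)
  x <- rnorm(50000)
  bank <- hermite_bank(5, 251)
  sp <- mt_spectrogram(x, bank)
  marg <- colMeans(sp$S)
  expect_lt(max(abs(marg / mean(marg) - 1)), 0.2)
})

test_that("surrogates preserve the Fourier modulus and total power exactly", {
  set.seed(8)
  for (n in c(64, 65, 500, 1001)) {
    x <- rnorm(n) * runif(1, 0.5, 5)
    s <- make_surrogates(x, 8, seed = n)
    mod0 <- Mod(stats::fft(x))
    for (j in 1:8) {
      expect_lt(max(abs(Mod(stats::fft(s[, j])) - mod0)),
                1e-9 * max(mod0))
    }
    expect_lt(max(abs(colMeans(s^2) - mean(x^2))), 1e-9)
  }
})

test_that("surrogate j is reproducible and independent of how many are drawn", {
  set.seed(10)
  x <- rnorm(200)
  a <- make_surrogates(x, 5, seed = 99)
  b <- make_surrogates(x, 2, seed = 99)
  expect_identical(a[, 1:2], b)
})

test_that("spectral_distance matches hand evaluation and is symmetric", {
  expect_equal(spectral_distance(c(1, 2, 3), c(1, 2, 3)), 0)

  G <- c(1, 1, 1, 1) / 4
  H <- c(2, 1, 1, 0) / 4
  expect_equal(spectral_distance(G, H), bf_spectral_distance(G, H),
               tolerance = 1e-10)

  set.seed(12)
  for (i in 1:100) {
    nf <- sample(4:64, 1)
    G <- runif(nf)
    H <- runif(nf)
    expect_equal(spectral_distance(G, H), bf_spectral_distance(G, H),
                 tolerance = 1e-10)
    expect_equal(spectral_distance(G, H), spectral_distance(H, G),
                 tolerance = 1e-12)
  }
  expect_error(spectral_distance(numeric(4), runif(4)), "positive total")
})

test_that("local-global divergences: constant case, brute force, permutation", {
  mk_spec <- function(S) {
    structure(list(tn = seq_len(nrow(S)), freqs = seq_len(ncol(S)) - 1,
                   S = S, K = 1L, Nh = 2L * ncol(S) - 1L, fs = 1),
              class = "mt_spectrogram")
  }
  Sconst <- matrix(rep(c(1, 2, 3, 4), each = 5), nrow = 5)
  expect_equal(local_global_distances(mk_spec(Sconst)), rep(0, 5))
  expect_equal(local_global_distances(mk_spec(matrix(0, 4, 6))), rep(0, 4))

  S2 <- rbind(c(1, 2, 3), c(3, 1, 1))
  gl <- colMeans(S2)
  want <- c(bf_spectral_distance(S2[1, ], gl),
            bf_spectral_distance(S2[2, ], gl))
  expect_equal(local_global_distances(mk_spec(S2)), want,
               tolerance = 1e-10)

  set.seed(14)
  S <- matrix(runif(8 * 12), 8, 12)
  c1 <- local_global_distances(mk_spec(S))
  c2 <- local_global_distances(mk_spec(S[sample(8), ]))
  expect_equal(sort(c1), sort(c2), tolerance = 1e-12)
})

test_that("theta_statistic is the population variance of the divergences", {
  expect_equal(theta_statistic(rep(0.7, 9)), 0)
  expect_equal(theta_statistic(c(0, 2)), 1)
  set.seed(16)
  for (i in 1:100) {
    cvec <- runif(sample(2:40, 1))
    expect_equal(theta_statistic(cvec), bf_theta(cvec), tolerance = 1e-10)
    a <- runif(1, 0.1, 10)
    expect_equal(theta_statistic(a * cvec), a^2 * theta_statistic(cvec),
                 tolerance = 1e-10)
  }
})

test_that("the observed statistic sits in the null bulk iff the signal is stationary", {
  set.seed(18)
  x <- rnorm(1024)
  r <- test_stationarity(x, K = 5, win_frac = 0.05, J = 50, seed = 181)
  expect_identical(r$decision, "stationary")
  expect_lt(r$theta1, stats::quantile(r$theta0, 0.95))
  expect_gt(mean(r$theta0 >= r$theta1), 0.05)

  set.seed(19)
  am <- sin(2 * pi * 3 * seq_len(1024) / 1024) * rnorm(1024)
  ra <- test_stationarity(am, K = 5, win_frac = 0.05, J = 50, seed = 182)
  expect_identical(ra$decision, "non-stationary")
  # far beyond the null's upper 1 - alpha quantile
  expect_gt(ra$theta1, stats::quantile(ra$theta0, 0.95))
  expect_gt(ra$INS, ra$INS_threshold)
  expect_gt(ra$INS, 1)
})

test_that("the surrogate null is stable and decisions do not depend on J", {
  set.seed(20)
  x <- rnorm(512)
  am <- sin(2 * pi * 3 * seq_len(512) / 512) * rnorm(512)

  r50 <- test_stationarity(x, J = 50, seed = 301)
  rA <- test_stationarity(x, J = 5000, seed = 302)
  rB <- test_stationarity(x, J = 5000, seed = 303)
  # mean theta0 under the null is stable across independent surrogate sets
  expect_lt(abs(mean(rA$theta0) - mean(rB$theta0)) / mean(rA$theta0), 0.05)
  # gamma-fitted threshold close to the empirical quantile at large J
  for (r in list(rA, rB)) {
    emp <- stats::quantile(r$theta0, 1 - r$alpha)
    expect_lt(abs(r$threshold - emp) / emp, 0.10)
  }
  expect_identical(r50$decision, rA$decision)

  a50 <- test_stationarity(am, J = 50, seed = 304)
  a5000 <- test_stationarity(am, J = 5000, seed = 305)
  expect_identical(a50$decision, a5000$decision)
  expect_identical(a5000$decision, "non-stationary")
})

test_that("a surrogate treated as the signal has a uniform null p-value", {
  set.seed(22)
  x <- rnorm(512)
  pvals <- numeric(200)
  for (i in 1:200) {
    s <- make_surrogates(x, 1, seed = 4000 + i)[, 1]
    r <- test_stationarity(s, K = 5, win_frac = 0.05, J = 50,
                           seed = 6000 + i)
    pvals[i] <- mean(r$theta0 >= r$theta1)
  }
  ks <- max(abs(sort(pvals) - (seq_along(pvals) - 0.5) / length(pvals)))
  expect_lt(ks, 0.15)
})

test_that("window too short or too long raises a length error", {
  expect_error(test_stationarity(rnorm(100), K = 5, win_frac = 0.05),
               "too short")
  expect_error(test_stationarity(rnorm(100), K = 5, win_frac = 2),
               "exceeds")
})

test_that("ins_curve tracks the window-size list and stays below threshold under the null", {
  expect_identical(nrow(ins_curve(rnorm(512), win_frac_list = numeric(0),
                                  J = 10)), 0L)
  set.seed(25)
  x <- rnorm(2048)
  curve <- ins_curve(x, K = 5, win_frac_list = c(0.03, 0.05, 0.075),
                     J = 50, seed = 25)
  expect_identical(nrow(curve), 3L)
  expect_true(all(curve$INS < curve$INS_threshold))
  expect_true(all(curve$decision == "stationary"))
})
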