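test_that("rms matches closed forms", {
  expect_equal(rms(numeric(10)), 0)
  expect_equal(rms(rep(-3, 7)), 3)
  tt <- (0:49999) / 5000
  expect_equal(rms(2.5 * sin(2 * pi * 100 * tt)), 2.5 / sqrt(2),
               tolerance = 1e-6)
  expect_error(rms(numeric(0)), "empty")
})

test_that("mean_puff averages and resamples as expected", {
  rec <- recording(rep(sin(2 * pi * 5 * (0:99) / 100), 4), fs = 100)
  iv <- cbind(c(0L, 100L, 200L, 300L), c(100L, 200L, 300L, 400L))
  ps <- puff_set(rec, iv)
  mp <- mean_puff(ps)
  expect_identical(mp$n_source, 4L)
  expect_equal(mp$curve, ps$segments[[1]], tolerance = 1e-9)

  # two opposite puffs cancel
  x <- c(sin(1:50), -sin(1:50))
  rec2 <- recording(x, fs = 100)
  ps2 <- puff_set(rec2, cbind(c(0L, 50L), c(50L, 100L)))
  expect_equal(max(abs(mean_puff(ps2)$curve)), 0, tolerance = 1e-12)

  expect_error(mean_puff(puff_set(rec, NULL)), "at least one")
})

test_that("mean puff recovers the generator template on clean data", {
  cfg <- sequence_preset("FSE-like", "coronal", duration = 5, noise_sd = 0,
                         am_depth = 0, jitter_sd = 0, lowpass_cutoff = NULL,
                         seed = 1)
  g <- generate_recording(cfg)
  mp <- mean_puff(puff_set(g$recording, g$truth))
  tt <- (seq_len(mp$L) - 1) / cfg$fs
  template <- exp(-cfg$decay * tt) * cos(2 * pi * cfg$carrier_freq * tt)
  expect_gt(stats::cor(mp$curve, template), 0.99)
})

test_that("puff_mse matches the normalized formula and is scale-invariant", {
  mk_mean <- function(curve) {
    rec <- recording(curve, fs = 100)
    mean_puff(puff_set(rec, cbind(0L, length(curve))), L = length(curve))
  }
  m <- mk_mean(c(0, 1, 0))
  expect_equal(puff_mse(c(0, 1, 0), m), 0)
  expect_equal(puff_mse(c(0, 0, 0), m), 1 / 3)

  set.seed(7)
  for (i in 1:20) {
    L <- sample(8:32, 1)
    mcurve <- rnorm(L)
    p <- rnorm(L)
    m1 <- mk_mean(mcurve)
    expect_equal(puff_mse(p, m1), bf_puff_mse(p, mcurve), tolerance = 1e-10)
    cc <- runif(1, 0.1, 10)
    expect_equal(puff_mse(cc * p, mk_mean(cc * mcurve)), puff_mse(p, m1),
                 tolerance = 1e-10)
  }
  expect_error(puff_mse(c(1, 2, 3), mk_mean(rep(1, 3))), "zero range")
})

test_that("Welch PSD integrates to the variance and locates line spectra", {
  zeros <- welch_psd(numeric(10000), fs = 1000)
  expect_equal(max(zeros$psd), 0)

  set.seed(3)
  x <- rnorm(250000)
  ps <- welch_psd(x, fs = 5000)
  df <- ps$freqs[2] - ps$freqs[1]
  expect_equal(sum(ps$psd) * df, stats::var(x), tolerance = 0.05)

  tt <- (0:49999) / 5000
  sine <- welch_psd(sin(2 * pi * 100 * tt), fs = 5000)
  expect_lt(abs(sine$freqs[which.max(sine$psd)] - 100),
            sine$freqs[2] - sine$freqs[1])

  expect_error(welch_psd(rnorm(10), fs = 100, seg_len = 20), "exceeds")
})

test_that("PSD of two concatenated identical halves matches the half's PSD", {
  set.seed(5)
  half <- rnorm(20000)
  p1 <- welch_psd(half, fs = 1000, seg_len = 1024)
  p2 <- welch_psd(c(half, half), fs = 1000, seg_len = 1024)
  expect_lt(mean(abs(p2$psd - p1$psd)) / mean(p1$psd), 0.2)
})

test_that("spectral moments match brute-force sums and two-line arithmetic", {
  # single line
  one <- list(freqs = c(0, 50, 100), psd = c(0, 4, 0))
  sp <- spectral_params(one)
  expect_equal(sp$f_mean, 50)
  expect_equal(sp$f_max, 50)
  expect_equal(sp$spec_sd, 0)
  # two equal lines
  two <- list(freqs = c(10, 20, 30, 40), psd = c(0, 3, 0, 3))
  sp2 <- spectral_params(two)
  expect_equal(sp2$f_mean, 30)
  expect_equal(sp2$spec_sd, 10)
  # random spectra vs oracle
  set.seed(11)
  for (i in 1:30) {
    nf <- sample(5:64, 1)
    f <- sort(runif(nf, 0, 500))
    P <- runif(nf)
    got <- spectral_params(list(freqs = f, psd = P))
    want <- bf_spectral_params(f, P)
    expect_equal(got$f_mean, want$f_mean, tolerance = 1e-10)
    expect_equal(got$f_max, want$f_max, tolerance = 1e-10)
    expect_equal(got$spec_sd, want$spec_sd, tolerance = 1e-10)
  }
  expect_error(spectral_params(list(freqs = 1:3, psd = numeric(3))),
               "zero")
})

test_that("per-puff mean frequency disperses across puffs when noise is present", {
  cfg <- sequence_preset("FSE-like", "coronal", duration = 5,
                         noise_sd = 0.1, seed = 21)
  g <- generate_recording(cfg)
  ps <- puff_set(zscore(g$recording), g$truth)
  fmeans <- vapply(ps$segments, function(seg) {
    spectral_params(welch_psd(seg, fs = ps$fs, seg_len = length(seg),
                              overlap = 0))$f_mean
  }, numeric(1))
  expect_gt(stats::sd(fmeans), 0)
})

test_that("RMS of the mean puff never exceeds the mean per-puff RMS", {
  set.seed(13)
  for (i in 1:10) {
    L <- sample(20:60, 1)
    n <- sample(3:8, 1)
    x <- rnorm(L * n)
    rec <- recording(x, fs = 100)
    iv <- cbind(seq(0L, by = L, length.out = n),
                seq(L, by = L, length.out = n))
    ps <- puff_set(rec, iv)
    mp <- mean_puff(ps, L = L)
    expect_lte(rms(mp$curve),
               mean(vapply(ps$segments, rms, numeric(1))) + 1e-12)
  }
})
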