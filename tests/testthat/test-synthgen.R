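test_that("generated recordings have the configured length and puff count", {
  cfg <- generator_config(fs = 5000, duration = 10, noise_sd = 0,
                          jitter_sd = 0, seed = 1)
  g <- generate_recording(cfg)
  expect_length(g$recording$samples, 50000L)

  cfg5 <- generator_config(fs = 5000, duration = 5, puff_period = 0.0625,
                           jitter_sd = 0, seed = 2)
  g5 <- generate_recording(cfg5)
  expect_identical(nrow(g5$truth), 80L)
})

test_that("zero-amplitude, zero-noise configuration yields an all-zero signal", {
  cfg <- generator_config(duration = 1, puff_amplitude = 0, noise_sd = 0,
                          am_depth = 0, jitter_sd = 0, seed = 1)
  g <- generate_recording(cfg)
  expect_equal(max(abs(g$recording$samples)), 0)
  expect_identical(nrow(g$truth), 16L)  # intervals still listed
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- sequence_preset("FSE-like", "axial", duration = 2, seed = 42)
  g1 <- generate_recording(cfg)
  g2 <- generate_recording(cfg)
  expect_identical(g1$recording$samples, g2$recording$samples)
  expect_identical(g1$truth, g2$truth)
})

test_that("doubling puff_amplitude doubles the RMS exactly when noiseless", {
  base <- list(duration = 2, noise_sd = 0, seed = 5, jitter_sd = 0.002)
  g1 <- generate_recording(do.call(generator_config, c(base, puff_amplitude = 1)))
  g2 <- generate_recording(do.call(generator_config, c(base, puff_amplitude = 2)))
  expect_equal(rms(g2$recording), 2 * rms(g1$recording), tolerance = 1e-12)
})

test_that("ground truth covers every sample where the noiseless train is nonzero", {
  cfg <- generator_config(duration = 2, noise_sd = 0, jitter_sd = 0.003,
                          lowpass_cutoff = NULL, seed = 9)
  g <- generate_recording(cfg)
  nz <- which(g$recording$samples != 0) - 1L  # 0-based
  covered <- unlist(lapply(seq_len(nrow(g$truth)), function(i) {
    seq.int(g$truth[i, 1L], g$truth[i, 2L] - 1L)
  }))
  expect_true(all(nz %in% covered))
  # intervals disjoint and sorted by construction
  expect_true(all(diff(g$truth[, 1L]) > 0))
  expect_true(all(g$truth[-1L, 1L] >= g$truth[-nrow(g$truth), 2L]))
})

test_that("PSD peak of a clean puff train sits within one Welch bin of the carrier", {
  for (ori in c("coronal", "axial")) {
    cfg <- sequence_preset("FSE-like", ori, duration = 5, noise_sd = 0,
                           am_depth = 0, jitter_sd = 0, seed = 3)
    g <- generate_recording(cfg)
    ps <- welch_psd(g$recording, seg_len = 512)
    f_peak <- ps$freqs[which.max(ps$psd)]
    expect_lt(abs(f_peak - cfg$carrier_freq), ps$freqs[2] - ps$freqs[1])
  }
})

test_that("the six presets are distinct and unknown names are rejected", {
  cfgs <- list()
  for (nm in c("FSE-like", "CINE-like")) {
    for (ori in c("coronal", "axial", "sagittal")) {
      cfgs[[paste(nm, ori)]] <- sequence_preset(nm, ori)
    }
  }
  carriers <- vapply(cfgs, `[[`, numeric(1), "carrier_freq")
  expect_identical(anyDuplicated(carriers), 0L)
  expect_lt(cfgs[["CINE-like coronal"]]$puff_duration,
            cfgs[["FSE-like coronal"]]$puff_duration)
  expect_false(cfgs[["FSE-like axial"]]$carrier_freq ==
                 cfgs[["FSE-like sagittal"]]$carrier_freq)
  expect_error(sequence_preset("SPIRAL", "coronal"), "unknown sequence")
  expect_error(sequence_preset("FSE-like", "oblique"), "unknown orientation")
})

test_that("invalid generator configurations name the violated constraint", {
  expect_error(generator_config(puff_duration = 0.1, puff_period = 0.05),
               "puff_duration < puff_period")
  expect_error(generator_config(am_depth = 1.5), "am_depth")
  expect_error(generator_config(lowpass_cutoff = 4000, fs = 5000),
               "lowpass_cutoff")
  expect_error(generator_config(fs = -1), "fs")
})
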