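#' Generator configuration for synthetic induced-potential recordings
#'
#' Describes a pseudo-periodic train of oscillatory bursts ("artefact
#' puffs") riding on a Gaussian noise floor, amplitude-modulated by a
#' low-frequency pseudo-sinusoid, and band-limited by a zero-phase low-pass
#' filter emulating the acquisition chain. Each puff is an exponentially
#' damped cosine `exp(-decay * t) * cos(2 * pi * carrier_freq * t)` of
#' length `puff_duration`, repeated every `puff_period` seconds with
#' optional Gaussian onset jitter (truncated at `puff_period / 4` so puffs
#' stay disjoint).
#'
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param puff_period seconds between puff onsets.
#' @param puff_duration seconds each puff lasts; must be below `puff_period`.
#' @param carrier_freq oscillation frequency of the burst, Hz.
#' @param decay exponential decay constant of the burst envelope, 1/s.
#' @param puff_amplitude peak amplitude of an unmodulated puff (arbitrary
#'   units).
#' @param am_frequency frequency in Hz of the low-frequency amplitude
#'   modulation applied multiplicatively to the puff train.
#' @param am_depth modulation depth in `[0, 1]`.
#' @param noise_sd standard deviation of the additive Gaussian noise floor.
#' @param lowpass_cutoff acquisition-bandwidth emulation: cutoff in Hz of a
#'   zero-phase Butterworth low-pass applied last; `NULL` disables it.
#' @param lowpass_order Butterworth order of that filter.
#' @param jitter_sd standard deviation in seconds of Gaussian puff-onset
#'   jitter (truncated at `puff_period / 4`).
#' @param baseline if `TRUE`, additionally add the slow additive baseline
#'   seen on real benches: a low-frequency sinusoid plus smoothed (1/f-ish)
#'   noise.
#' @param baseline_amplitude amplitude of the additive baseline sinusoid.
#' @param baseline_frequency its frequency in Hz.
#' @param label,orientation metadata copied onto generated recordings.
#' @param seed integer seed; identical config (including seed) gives
#'   bit-identical output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(fs = 5000, duration = 10,
                             puff_period = 0.0625, puff_duration = 0.030,
                             carrier_freq = 250, decay = 2 / puff_duration,
                             puff_amplitude = 1,
                             am_frequency = 1.2, am_depth = 0.3,
                             noise_sd = 0.1,
                             lowpass_cutoff = 350, lowpass_order = 4,
                             jitter_sd = 0,
                             baseline = FALSE, baseline_amplitude = 0.5,
                             baseline_frequency = 0.7,
                             label = "custom", orientation = "none",
                             seed = 1L) {
  cfg <- structure(
    list(fs = fs, duration = duration, puff_period = puff_period,
         puff_duration = puff_duration, carrier_freq = carrier_freq,
         decay = decay, puff_amplitude = puff_amplitude,
         am_frequency = am_frequency, am_depth = am_depth,
         noise_sd = noise_sd, lowpass_cutoff = lowpass_cutoff,
         lowpass_order = lowpass_order, jitter_sd = jitter_sd,
         baseline = isTRUE(baseline),
         baseline_amplitude = baseline_amplitude,
         baseline_frequency = baseline_frequency,
         label = label, orientation = orientation,
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  for (f in c("fs", "duration", "puff_period", "puff_duration",
              "carrier_freq", "decay", "puff_amplitude", "am_frequency",
              "am_depth", "noise_sd", "jitter_sd")) {
    assert_scalar_num(cfg[[f]], f)
  }
  if (cfg$fs <= 0) stop_config("fs must be > 0")
  if (cfg$duration <= 0) stop_config("duration must be > 0")
  if (!(cfg$puff_duration > 0 && cfg$puff_duration < cfg$puff_period)) {
    stop_config("need 0 < puff_duration < puff_period, got puff_duration=",
                cfg$puff_duration, ", puff_period=", cfg$puff_period)
  }
  if (cfg$am_depth < 0 || cfg$am_depth > 1) {
    stop_config("am_depth must be in [0, 1], got ", cfg$am_depth)
  }
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (cfg$jitter_sd < 0) stop_config("jitter_sd must be >= 0")
  if (!is.null(cfg$lowpass_cutoff)) {
    assert_scalar_num(cfg$lowpass_cutoff, "lowpass_cutoff")
    if (cfg$lowpass_cutoff <= 0 || cfg$lowpass_cutoff >= cfg$fs / 2) {
      stop_config("lowpass_cutoff must satisfy 0 < cutoff < fs/2, got ",
                  cfg$lowpass_cutoff, " at fs=", cfg$fs)
    }
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> %s/%s: fs=%g Hz, %g s, ",
                     "period=%g s, puff=%g s @ %g Hz, seed=%d\n"),
              x$label, x$orientation, x$fs, x$duration, x$puff_period,
              x$puff_duration, x$carrier_freq, x$seed))
  invisible(x)
}

# The six synthetic sequence-by-orientation variants. Periods give 80 puffs
# per 5 s; CINE-like puffs are much shorter than FSE-like ones, and carrier
# frequencies per orientation sit in distinct bands so the variants are
# spectrally distinguishable.
preset_table <- function() {
  list(
    "fse-like" = list(
      puff_duration = 0.030, am_frequency = 1.2, am_depth = 0.3,
      carriers = c(coronal = 250, axial = 90, sagittal = 140)),
    "cine-like" = list(
      puff_duration = 0.008, am_frequency = 0.8, am_depth = 0.2,
      carriers = c(coronal = 225, axial = 275, sagittal = 234))
  )
}

#' Sequence/orientation presets for the synthetic generator
#'
#' Returns a fully populated [generator_config()] for one of six variants:
#' two pulse-sequence families (`"FSE-like"` with long puffs, `"CINE-like"`
#' with very short ones) by three slice orientations, each with a distinct
#' burst carrier frequency. All presets use fs = 5000 Hz, 10 s duration and
#' a puff every 0.0625 s (80 puffs per 5 s).
#'
#' @param name `"FSE-like"` or `"CINE-like"` (case-insensitive).
#' @param orientation `"coronal"`, `"axial"` or `"sagittal"`.
#' @param ... overrides passed on to [generator_config()] (e.g. `seed`,
#'   `noise_sd`, `duration`).
#' @return A `generator_config`.
#' @export
sequence_preset <- function(name, orientation, ...) {
  key <- tolower(as.character(name)[1])
  tab <- preset_table()
  if (!key %in% names(tab)) {
    stop_config("unknown sequence preset '", name, "'; available: ",
                paste(names(tab), collapse = ", "))
  }
  ori <- tolower(as.character(orientation)[1])
  p <- tab[[key]]
  if (!ori %in% names(p$carriers)) {
    stop_config("unknown orientation '", orientation, "'; available: ",
                paste(names(p$carriers), collapse = ", "))
  }
  args <- list(fs = 5000, duration = 10, puff_period = 0.0625,
               puff_duration = p$puff_duration,
               carrier_freq = unname(p$carriers[ori]),
               decay = 2 / p$puff_duration, puff_amplitude = 1,
               am_frequency = p$am_frequency, am_depth = p$am_depth,
               noise_sd = 0.1, lowpass_cutoff = 350, jitter_sd = 0.002,
               label = if (key == "fse-like") "FSE-like" else "CINE-like",
               orientation = ori)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

#' Generate a synthetic induced-potential recording
#'
#' Builds the puff train described by a [generator_config()]: damped-cosine
#' bursts at (optionally jittered) periodic onsets, multiplied by the
#' low-frequency amplitude modulation `1 + am_depth * sin(2 pi f_am t)`,
#' plus the optional additive slow baseline, plus Gaussian noise, with the
#' zero-phase low-pass applied last. Ground-truth puff boundaries (0-based
#' half-open sample intervals, pre-filter) are returned alongside.
#'
#' @param config a `generator_config`.
#' @return A list with elements `recording` (a [recording]) and `truth`
#'   (two-column integer matrix of `[start, end)` puff intervals).
#' @export
generate_recording <- function(config) {
  validate_generator_config(config)
  c_ <- config
  n <- round(c_$fs * c_$duration)
  tvec <- (seq_len(n) - 1) / c_$fs
  set.seed(c_$seed)

  n_puffs <- floor(c_$duration / c_$puff_period)
  dur_samp <- max(1L, round(c_$puff_duration * c_$fs))
  tt <- (seq_len(dur_samp) - 1) / c_$fs
  template <- exp(-c_$decay * tt) * cos(2 * pi * c_$carrier_freq * tt)

  jitter <- if (c_$jitter_sd > 0) {
    j <- stats::rnorm(n_puffs, 0, c_$jitter_sd)
    pmax(pmin(j, c_$puff_period / 4), -c_$puff_period / 4)
  } else rep(0, n_puffs)

  train <- numeric(n)
  truth <- matrix(integer(0), ncol = 2L)
  for (k in seq_len(n_puffs)) {
    onset <- round(((k - 1) * c_$puff_period + jitter[k]) * c_$fs)
    onset <- max(onset, 0)
    end <- min(onset + dur_samp, n)
    if (end <= onset) next
    idx <- (onset + 1):end
    train[idx] <- train[idx] + c_$puff_amplitude * template[seq_along(idx)]
    truth <- rbind(truth, c(onset, end))
  }
  truth <- validate_intervals(truth, n, "ground truth")

  if (c_$am_depth > 0) {
    train <- train * (1 + c_$am_depth * sin(2 * pi * c_$am_frequency * tvec))
  }
  x <- train
  if (c_$baseline) {
    slow <- stats::rnorm(n)
    # heavy moving-average smoothing gives a wandering low-frequency floor
    w <- max(3L, round(c_$fs / 10))
    slow <- stats::filter(slow, rep(1 / w, w), circular = TRUE)
    slow <- as.numeric(slow) / stats::sd(slow) * 0.3 * c_$baseline_amplitude
    x <- x + c_$baseline_amplitude *
      sin(2 * pi * c_$baseline_frequency * tvec) + slow
  }
  if (c_$noise_sd > 0) x <- x + stats::rnorm(n, 0, c_$noise_sd)
  if (!is.null(c_$lowpass_cutoff)) {
    bf <- signal::butter(c_$lowpass_order,
                         c_$lowpass_cutoff / (c_$fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  rec <- recording(x, c_$fs, label = c_$label, orientation = c_$orientation,
                   source = sprintf("synthetic seed=%d", c_$seed))
  list(recording = rec, truth = truth)
}
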