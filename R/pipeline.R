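# Study driver: run the global (whole recording) and local (per puff)
# analyses over a set of recordings or synthetic presets and aggregate the
# results into report tables.

#' Study configuration
#'
#' @param inputs list of input descriptors. Each element is a list with
#'   either `preset` and `orientation` (synthetic generation via
#'   [sequence_preset()]) or `path` (a recording file, optionally with
#'   `annotations`, a puff-annotation file), plus an optional `label`.
#'   Default: the six synthetic sequence-by-orientation presets.
#' @param analysis_window seconds of each recording analyzed (from the
#'   start); default 5.
#' @param puff_source `"auto"` (envelope segmentation), `"annotations"`
#'   (requires an annotation file per input) or `"truth"` (synthetic
#'   inputs only: use the generator's ground-truth boundaries).
#' @param seg_params a [segmentation_params()].
#' @param kpss list of KPSS options: `variant`, `nlags`, `alpha`,
#'   `critical_value`.
#' @param tf list of time-frequency-test options: `K`, `J`, `win_frac`
#'   (vector; the first value is used for the global decision),
#'   `puff_win_frac` (window fraction for per-puff tests, relative to the
#'   puff length), `alpha`, `sqrt_ins`.
#' @param welch list of Welch options for the global PSD: `seg_len`,
#'   `overlap`.
#' @param band optional `c(f_lo, f_hi)` restriction for spectral moments.
#' @param out_dir if non-`NULL`, report tables are written there.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it, so a rerun with the same config is identical.
#' @return An object of class `study_config`.
#' @export
study_config <- function(inputs = NULL, analysis_window = 5,
                         puff_source = c("auto", "annotations", "truth"),
                         seg_params = segmentation_params(),
                         kpss = list(), tf = list(), welch = list(),
                         band = NULL, out_dir = NULL, seed = 1L) {
  if (is.null(inputs)) {
    inputs <- list()
    for (nm in c("FSE-like", "CINE-like")) {
      for (ori in c("coronal", "axial", "sagittal")) {
        inputs[[length(inputs) + 1L]] <- list(preset = nm, orientation = ori)
      }
    }
  }
  inputs <- lapply(inputs, function(inp) {
    if (is.null(inp$label)) {
      inp$label <- if (!is.null(inp$preset)) {
        paste(inp$preset, inp$orientation, sep = "/")
      } else basename(inp$path)
    }
    inp
  })
  labels <- vapply(inputs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_config("input labels must be unique")
  for (inp in inputs) {
    if (!is.null(inp$path) && !file.exists(inp$path)) {
      stop_config("input file not found: ", inp$path)
    }
  }
  kpss <- utils::modifyList(
    list(variant = "trend", nlags = NULL, alpha = 0.05,
         critical_value = NULL), kpss)
  tf <- utils::modifyList(
    list(K = 5, J = 5000, win_frac = c(0.03, 0.04, 0.05, 0.07, 0.075),
         puff_win_frac = 0.2, alpha = 0.05, sqrt_ins = TRUE), tf)
  welch <- utils::modifyList(list(seg_len = 4096, overlap = 0.5), welch)
  structure(list(inputs = inputs, analysis_window = analysis_window,
                 puff_source = match.arg(puff_source),
                 seg_params = seg_params, kpss = kpss, tf = tf,
                 welch = welch, band = band, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML maps directly onto the arguments of [study_config()].
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(study_config)))]
  if (!is.null(args$seg_params)) {
    args$seg_params <- do.call(segmentation_params, args$seg_params)
  }
  do.call(study_config, args)
}

# Crop a recording to its first `seconds` seconds (and any intervals with
# it), without going past the end.
crop_recording <- function(rec, seconds, intervals = NULL) {
  n <- min(length(rec$samples), round(seconds * rec$fs))
  rec$samples <- rec$samples[seq_len(n)]
  if (!is.null(intervals) && nrow(intervals) > 0L) {
    intervals <- intervals[intervals[, 2L] <= n, , drop = FALSE]
  }
  list(rec = rec, intervals = intervals)
}

na_result <- function() {
  list(stat = NA_real_, decision = NA_character_)
}

analyze_one_recording <- function(inp, cfg, idx) {
  if (!is.null(inp$preset)) {
    gen_cfg <- sequence_preset(inp$preset, inp$orientation,
                               seed = derive_seed(cfg$seed, idx))
    gen <- generate_recording(gen_cfg)
    rec <- gen$recording
    truth <- gen$truth
  } else {
    rec <- read_recording(inp$path, fs_override = inp$fs)
    truth <- NULL
  }
  cr <- crop_recording(rec, cfg$analysis_window, truth)
  rec <- zscore(cr$rec)
  truth <- cr$intervals

  # --- global analysis -----------------------------------------------------
  g_rms <- rms(rec)
  psd <- welch_psd(rec, seg_len = min(cfg$welch$seg_len,
                                      length(rec$samples)),
                   overlap = cfg$welch$overlap)
  g_spec <- spectral_params(psd, band = cfg$band)
  g_kpss <- kpss_test(rec, variant = cfg$kpss$variant,
                      nlags = cfg$kpss$nlags, alpha = cfg$kpss$alpha,
                      critical_value = cfg$kpss$critical_value)
  g_tf <- test_stationarity(rec, K = cfg$tf$K,
                            win_frac = cfg$tf$win_frac[1], J = cfg$tf$J,
                            alpha = cfg$tf$alpha,
                            seed = derive_seed(cfg$seed, 1000L + idx),
                            sqrt_ins = cfg$tf$sqrt_ins)

  # --- puff extraction -----------------------------------------------------
  puffs <- switch(cfg$puff_source,
    auto = segment_puffs(rec, cfg$seg_params),
    annotations = {
      if (is.null(inp$annotations)) {
        stop_config("puff_source='annotations' but input '", inp$label,
                    "' has no annotation file")
      }
      puffs_from_annotations(rec, read_annotations(inp$annotations, rec))
    },
    truth = {
      if (is.null(truth)) {
        stop_config("puff_source='truth' needs a synthetic preset input")
      }
      puff_set(rec, truth)
    })

  # --- local (per-puff) analysis -------------------------------------------
  n_puffs <- length(puffs)
  mp <- if (n_puffs > 0L) mean_puff(puffs) else NULL
  rows <- vector("list", n_puffs)
  for (i in seq_len(n_puffs)) {
    seg <- puffs$segments[[i]]
    p_rms <- rms(seg)
    p_mse <- tryCatch(puff_mse(seg, mp), error = function(e) NA_real_)
    p_spec <- tryCatch({
      ps <- welch_psd(seg, fs = puffs$fs, seg_len = length(seg),
                      overlap = 0)
      spectral_params(ps, band = cfg$band)
    }, error = function(e) list(f_mean = NA_real_, f_max = NA_real_,
                                spec_sd = NA_real_))
    p_kpss <- tryCatch(
      kpss_test(seg, variant = cfg$kpss$variant, nlags = cfg$kpss$nlags,
                alpha = cfg$kpss$alpha,
                critical_value = cfg$kpss$critical_value),
      error = function(e) NULL)
    p_tf <- tryCatch(
      test_stationarity(seg, K = cfg$tf$K, win_frac = cfg$tf$puff_win_frac,
                        J = cfg$tf$J, alpha = cfg$tf$alpha,
                        seed = derive_seed(cfg$seed, 2000L + 100L * idx + i),
                        sqrt_ins = cfg$tf$sqrt_ins),
      error = function(e) structure(list(msg = conditionMessage(e)),
                                    class = "tf_skip"))
    skipped <- inherits(p_tf, "tf_skip")
    rows[[i]] <- data.frame(
      label = inp$label, puff = i,
      start = puffs$intervals[i, 1L], end = puffs$intervals[i, 2L],
      length = length(seg), rms = p_rms, mse = p_mse,
      f_mean = p_spec$f_mean, f_max = p_spec$f_max,
      spec_sd = p_spec$spec_sd,
      kpss_stat = if (is.null(p_kpss)) NA_real_ else p_kpss$statistic,
      kpss_decision = if (is.null(p_kpss)) NA_character_ else
        p_kpss$decision,
      theta1 = if (skipped) NA_real_ else p_tf$theta1,
      tf_threshold = if (skipped) NA_real_ else p_tf$threshold,
      INS = if (skipped) NA_real_ else p_tf$INS,
      INS_threshold = if (skipped) NA_real_ else p_tf$INS_threshold,
      tf_decision = if (skipped) "not-computable" else p_tf$decision,
      tf_skip_reason = if (skipped) p_tf$msg else NA_character_,
      stringsAsFactors = FALSE)
  }
  puff_records <- if (n_puffs > 0L) do.call(rbind, rows) else NULL

  global_row <- data.frame(
    label = inp$label, n_samples = length(rec$samples), fs = rec$fs,
    rms = g_rms, f_mean = g_spec$f_mean, f_max = g_spec$f_max,
    spec_sd = g_spec$spec_sd, kpss_stat = g_kpss$statistic,
    kpss_critical = g_kpss$critical_value, kpss_decision = g_kpss$decision,
    theta1 = g_tf$theta1, tf_threshold = g_tf$threshold, INS = g_tf$INS,
    INS_threshold = g_tf$INS_threshold, tf_decision = g_tf$decision,
    n_puffs = n_puffs, stringsAsFactors = FALSE)

  list(global = global_row, puffs = puff_records)
}

# min/max/mean/sd of a per-puff column, NA-tolerant; all NA -> NAs.
aggregate_column <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(c(min = NA_real_, max = NA_real_, mean = NA_real_,
             sd = NA_real_))
  }
  c(min = min(v), max = max(v), mean = mean(v),
    sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
}

fmt_cell <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

# Formatted layout table for one measure: rows Global (optional),
# [min-max], Mean-stdev; one column per recording label.
layout_table <- function(agg, global = NULL) {
  cols <- lapply(names(agg), function(lab) {
    a <- agg[[lab]]
    vals <- c(
      if (!is.null(global)) fmt_cell(global[[lab]]),
      sprintf("[%s-%s]", fmt_cell(a["min"]), fmt_cell(a["max"])),
      sprintf("%s-%s", fmt_cell(a["mean"]), fmt_cell(a["sd"])))
    vals
  })
  df <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  names(df) <- names(agg)
  rn <- c(if (!is.null(global)) "Global", "[min-max]", "Mean-stdev")
  cbind(data.frame(row = rn, stringsAsFactors = FALSE), df)
}

#' Run the full characterization study
#'
#' For every input recording (loaded or generated): Z-score normalization
#' of the first `analysis_window` seconds, global RMS / Welch spectral
#' moments / KPSS / time-frequency stationarity test, puff extraction, and
#' the same features plus both stationarity tests per puff (the
#' time-frequency test is marked not-computable for puffs shorter than the
#' smallest admissible analysis window). Failures in one input or puff are
#' recorded and do not abort the study.
#'
#' @param cfg a [study_config()].
#' @return An object of class `study_report`: `global` (one row per
#'   recording), `puffs` (per-puff records, one data frame per label),
#'   `aggregates` (numeric min/max/mean/sd per measure and label),
#'   `tables` (formatted report tables: rms, mse, spectral, kpss, tf),
#'   `errors` (data frame of recorded failures) and `config`. If
#'   `cfg$out_dir` is set the tables and records are also written there via
#'   [write_report()].
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  results <- list()
  errors <- data.frame(label = character(0), stage = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  for (idx in seq_along(cfg$inputs)) {
    inp <- cfg$inputs[[idx]]
    res <- tryCatch(analyze_one_recording(inp, cfg, idx),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(
        label = inp$label, stage = "recording",
        message = conditionMessage(res), stringsAsFactors = FALSE))
    } else {
      results[[inp$label]] <- res
    }
  }
  global <- do.call(rbind, lapply(results, `[[`, "global"))
  rownames(global) <- NULL
  puffs <- lapply(results, `[[`, "puffs")

  measures <- c("rms", "mse", "f_mean", "f_max", "spec_sd", "kpss_stat",
                "theta1", "tf_threshold", "INS", "INS_threshold")
  aggregates <- list()
  for (meas in measures) {
    aggregates[[meas]] <- lapply(puffs, function(df) {
      if (is.null(df)) aggregate_column(numeric(0)) else
        aggregate_column(df[[meas]])
    })
  }
  gcol <- function(col) {
    if (is.null(global)) list() else
      stats::setNames(as.list(global[[col]]), global$label)
  }
  tables <- list(
    rms = layout_table(aggregates$rms, gcol("rms")),
    mse = layout_table(aggregates$mse),
    f_mean = layout_table(aggregates$f_mean, gcol("f_mean")),
    f_max = layout_table(aggregates$f_max, gcol("f_max")),
    spec_sd = layout_table(aggregates$spec_sd, gcol("spec_sd")),
    kpss = layout_table(aggregates$kpss_stat, gcol("kpss_stat")),
    theta = layout_table(aggregates$theta1, gcol("theta1")),
    ins = layout_table(aggregates$INS, gcol("INS")))

  report <- structure(list(global = global, puffs = puffs,
                           aggregates = aggregates, tables = tables,
                           errors = errors, config = cfg),
                      class = "study_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(tables, file.path(cfg$out_dir, "report"))
    jsonlite::write_json(
      list(global = global, puffs = puffs, errors = errors),
      file.path(cfg$out_dir, "records.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = I(17), na = "null",
      pretty = TRUE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d recordings, %d failed\n",
              if (is.null(x$global)) 0L else nrow(x$global),
              nrow(x$errors)))
  if (!is.null(x$global)) {
    print(x$global[, c("label", "rms", "f_mean", "kpss_stat",
                       "kpss_decision", "INS", "INS_threshold",
                       "tf_decision", "n_puffs")], digits = 4)
  }
  invisible(x)
}
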