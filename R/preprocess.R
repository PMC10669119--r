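#' Z-score normalization
#'
#' Centers and scales a recording to zero mean and unit standard deviation,
#' `Y = (X - mu) / sigma`, so that recordings from different sequences and
#' slice orientations are on comparable amplitude scales. The sample (n-1)
#' standard deviation is used.
#'
#' @param rec a [recording] or numeric vector.
#' @return Same type as the input, normalized.
#' @export
zscore <- function(rec) {
  x <- as_samples(rec)
  if (length(x) < 2L) stop_degenerate("zscore needs at least 2 samples")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_degenerate("zscore undefined for a constant signal (sd = 0)")
  }
  y <- (x - mean(x)) / s
  if (inherits(rec, "recording")) {
    rec$samples <- y
    rec
  } else y
}

#' Segmentation parameters for automatic puff extraction
#'
#' The automatic segmenter computes a moving-RMS envelope and thresholds it
#' at `median(envelope) + threshold_k * mad(envelope)`; the robust baseline
#' (median/MAD rather than mean/SD) tolerates the fact that the
#' high-amplitude bursts dominate non-robust moments.
#'
#' @param envelope_window moving-RMS window length in seconds.
#' @param threshold_k core-detection threshold in multiples of the MAD
#'   above the median.
#' @param extend_k extension (offset) threshold in multiples of the
#'   noise-floor spread above the noise floor; see [segment_puffs()].
#' @param min_duration shortest interval kept, seconds.
#' @param min_gap gaps shorter than this are merged, seconds.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(envelope_window = 0.005, threshold_k = 1.5,
                                extend_k = 3, min_duration = 0.005,
                                min_gap = 0.005) {
  p <- list(envelope_window = envelope_window, threshold_k = threshold_k,
            extend_k = extend_k, min_duration = min_duration,
            min_gap = min_gap)
  for (f in names(p)) {
    assert_scalar_num(p[[f]], f)
    if (p[[f]] <= 0) stop_config(f, " must be positive")
  }
  structure(p, class = "segmentation_params")
}

#' Construct a puff set
#'
#' A `puff_set` couples validated `[start, end)` intervals with the actual
#' per-puff sample slices of the parent recording.
#'
#' @param rec parent [recording].
#' @param intervals two-column matrix of 0-based half-open sample intervals.
#' @return An object of class `puff_set` with fields `intervals`,
#'   `segments` (list of numeric vectors), `fs` and `parent_label`.
#' @export
puff_set <- function(rec, intervals) {
  stopifnot(inherits(rec, "recording"))
  m <- validate_intervals(intervals, length(rec$samples), "puff set")
  segments <- lapply(seq_len(nrow(m)), function(i) {
    rec$samples[(m[i, 1L] + 1L):m[i, 2L]]
  })
  structure(list(intervals = m, segments = segments, fs = rec$fs,
                 parent_label = paste(rec$label, rec$orientation)),
            class = "puff_set")
}

#' @export
print.puff_set <- function(x, ...) {
  cat(sprintf("<puff_set> %d puffs (%s), fs=%g Hz\n",
              nrow(x$intervals), x$parent_label, x$fs))
  invisible(x)
}

#' @export
length.puff_set <- function(x) nrow(x$intervals)

# Centered moving RMS; partial windows at the edges use the samples present.
moving_rms <- function(x, w) {
  n <- length(x)
  w <- min(as.integer(w), n)
  cs <- cumsum(c(0, x^2))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Automatic puff segmentation
#'
#' An envelope double-threshold stand-in for manual puff delineation. A
#' centered moving-RMS envelope is computed; burst *cores* are the runs
#' where it exceeds `median + threshold_k * MAD` (robust against the
#' bursts themselves dominating the envelope). Because the bursts decay
#' gradually into the noise floor, each core is then *extended* outward,
#' Schmitt-trigger style, for as long as the envelope stays above a low
#' offset threshold `floor + extend_k * spread`, where `floor` is the 10th
#' percentile of the envelope (the noise floor) and `spread` the MAD of
#' the sub-median envelope values. Finally gaps shorter than `min_gap` are
#' merged and intervals shorter than `min_duration` dropped.
#'
#' @param rec a [recording].
#' @param params a [segmentation_params()].
#' @return A [puff_set()].
#' @export
segment_puffs <- function(rec, params = segmentation_params()) {
  stopifnot(inherits(rec, "recording"), inherits(params, "segmentation_params"))
  n <- length(rec$samples)
  w <- round(params$envelope_window * rec$fs)
  if (w < 1L) w <- 1L
  if (w > n) stop_config("envelope_window (", w, " samples) is longer than ",
                         "the recording (", n, " samples)")
  env <- moving_rms(rec$samples, w)
  med <- stats::median(env)
  thr <- med + params$threshold_k * stats::mad(env)
  low <- env[env <= med]
  thr_low <- stats::quantile(env, 0.1, names = FALSE) +
    params$extend_k * stats::mad(low, center = stats::median(low))
  thr_low <- min(thr_low, thr)
  core <- is.finite(thr) & env > thr
  # hysteresis: extend every above-core sample while env stays above thr_low
  above <- core
  if (any(core) && thr_low < thr) {
    ok <- env > thr_low
    r0 <- rle(ok)
    e0 <- cumsum(r0$lengths)
    s0 <- e0 - r0$lengths + 1L
    for (i in which(r0$values)) {
      if (any(core[s0[i]:e0[i]])) above[s0[i]:e0[i]] <- TRUE
    }
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values] - 1L, ends[r$values])  # 0-based half-open
  if (nrow(iv) > 1L) {
    min_gap <- round(params$min_gap * rec$fs)
    keep <- list(iv[1L, ])
    for (i in 2:nrow(iv)) {
      last <- keep[[length(keep)]]
      if (iv[i, 1L] - last[2L] < min_gap) {
        keep[[length(keep)]] <- c(last[1L], iv[i, 2L])
      } else keep[[length(keep) + 1L]] <- iv[i, ]
    }
    iv <- do.call(rbind, keep)
  }
  # the centered moving-RMS window widens every burst's support by about
  # w/2 on each side; pull the boundaries back in by that amount
  shrink <- w %/% 2L
  if (nrow(iv) > 0L && shrink > 0L) {
    wide <- (iv[, 2L] - iv[, 1L]) > 2L * shrink
    iv[wide, 1L] <- iv[wide, 1L] + shrink
    iv[wide, 2L] <- iv[wide, 2L] - shrink
  }
  if (nrow(iv) > 0L) {
    min_dur <- round(params$min_duration * rec$fs)
    iv <- iv[(iv[, 2L] - iv[, 1L]) >= min_dur, , drop = FALSE]
  }
  puff_set(rec, iv)
}

#' Build a puff set from imported annotations
#'
#' @param rec a [recording].
#' @param ann an [annotation_set()] valid for `rec` (e.g. a manual
#'   segmentation read with [read_annotations()]).
#' @return A [puff_set()] with exactly the annotated intervals.
#' @export
puffs_from_annotations <- function(rec, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (ann$n_samples != length(rec$samples)) {
    stop_format("annotation set was validated against a recording of ",
                ann$n_samples, " samples, not ", length(rec$samples))
  }
  puff_set(rec, ann$intervals)
}
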