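#' Construct a recording
#'
#' A `recording` holds a single-channel voltage trace together with its
#' sampling rate and acquisition metadata (MRI sequence label and slice
#' orientation). Amplitudes are carried in arbitrary units: downstream
#' analyses normalize, so the unit string is purely informational.
#'
#' @param samples numeric vector of sampled voltages (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param label sequence identifier (e.g. `"FSE-like"`).
#' @param orientation slice-orientation identifier (e.g. `"coronal"`).
#' @param source free-text provenance (file path, generator call, ...).
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, label = "", orientation = "",
                      source = "") {
  samples <- as.numeric(samples)
  assert_scalar_num(fs, "fs")
  if (fs <= 0) stop_config("fs must be positive, got ", fs)
  if (length(samples) < 1L) stop_format("a recording needs at least 1 sample")
  if (any(!is.finite(samples))) stop_format("samples must all be finite")
  structure(
    list(samples = samples, fs = fs, label = as.character(label),
         orientation = as.character(orientation),
         source = as.character(source)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples @ %g Hz (%.4g s)",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (nzchar(x$label)) cat(" | ", x$label, sep = "")
  if (nzchar(x$orientation)) cat("/", x$orientation, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$samples)

#' Read a recording from delimited text
#'
#' Accepts one-column files (one sample value per line) or two-column files
#' (time in seconds, value). Lines starting with `#` are header lines; the
#' headers `# fs=<Hz>`, `# sequence=<label>` and `# orientation=<label>` are
#' recognized. For two-column input the time column must be uniformly
#' sampled (relative deviation of successive steps below 1e-6) and the
#' sampling rate is inferred as `1/dt` unless overridden.
#'
#' @param path file to read.
#' @param fs_override sampling rate in Hz, taking precedence over any header
#'   or inferred value.
#' @return A [recording].
#' @export
read_recording <- function(path, fs_override = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^\\s*#", lines)
  meta <- list(fs = NULL, sequence = "", orientation = "")
  for (h in sub("^\\s*#\\s*", "", lines[hdr])) {
    kv <- regmatches(h, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(kv) == 3L) {
      key <- tolower(kv[2]); val <- trimws(kv[3])
      if (key == "fs") meta$fs <- suppressWarnings(as.numeric(val))
      if (key == "sequence") meta$sequence <- val
      if (key == "orientation") meta$orientation <- val
    }
  }
  body <- lines[!hdr]
  if (length(body) == 0L) stop_format("no data lines in ", path)
  fields <- strsplit(trimws(body), "[,;\t ]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !ncol %in% c(1L, 2L)) {
    stop_format(path, ": expected 1 or 2 numeric columns on every line")
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (any(is.na(vals))) stop_format(path, ": non-numeric data line")
  if (ncol == 1L) {
    samples <- vals
    fs <- fs_override %||% meta$fs
    if (is.null(fs) || is.na(fs)) {
      stop_config(path, ": no sampling rate (no '# fs=' header and no ",
                  "fs_override)")
    }
  } else {
    m <- matrix(vals, ncol = 2L, byrow = TRUE)
    tt <- m[, 1L]; samples <- m[, 2L]
    if (length(tt) < 2L) stop_format(path, ": two-column input needs >= 2 rows")
    dt <- diff(tt)
    if (any(dt <= 0) || (max(dt) - min(dt)) / mean(dt) > 1e-6) {
      stop_format(path, ": time column is not uniformly sampled")
    }
    fs <- fs_override %||% (1 / mean(dt))
  }
  recording(samples, fs, label = meta$sequence,
            orientation = meta$orientation, source = path)
}

#' Write a recording to delimited text
#'
#' One sample value per line, preceded by `# fs=`, `# sequence=` and
#' `# orientation=` header lines. Values are written with 15 significant
#' digits so that a write/read round trip preserves them to better than
#' 1e-12 relative.
#'
#' @param rec a [recording].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.15g", rec$fs),
               paste0("# sequence=", rec$label),
               paste0("# orientation=", rec$orientation),
               sprintf("%.15g", rec$samples)), con)
  invisible(path)
}

#' Read puff annotations
#'
#' Reads a two-column delimited text file of 0-based half-open
#' `[start, end)` sample-index intervals (one puff per row) and validates it
#' against a recording: rows must be sorted, pairwise disjoint and inside
#' `[0, length(rec))`.
#'
#' @param path file of two integer columns (start, end); `#` lines ignored.
#' @param rec the [recording] the annotations refer to.
#' @return An object of class `annotation_set` (two-column integer matrix
#'   wrapper).
#' @export
read_annotations <- function(path, rec) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) return(annotation_set(NULL, rec))
  fields <- strsplit(trimws(lines), "[,;\t ]+")
  if (any(lengths(fields) != 2L)) {
    stop_format(path, ": every annotation row needs exactly 2 columns")
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (any(is.na(vals)) || any(vals != round(vals))) {
    stop_format(path, ": annotation indices must be integers")
  }
  annotation_set(matrix(vals, ncol = 2L, byrow = TRUE), rec)
}

#' Construct a validated annotation set
#'
#' @param intervals two-column matrix (or list of pairs) of 0-based
#'   half-open sample intervals; `NULL` for an empty set.
#' @param rec the parent [recording].
#' @return An `annotation_set`.
#' @export
annotation_set <- function(intervals, rec) {
  stopifnot(inherits(rec, "recording"))
  m <- validate_intervals(intervals, length(rec$samples), "annotation set")
  structure(list(intervals = m, n_samples = length(rec$samples)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d intervals over %d samples\n",
              nrow(x$intervals), x$n_samples))
  invisible(x)
}

#' Write intervals (annotations or puff boundaries) to delimited text
#'
#' Two comma-separated integer columns, 0-based half-open, one row per puff,
#' readable back with [read_annotations()]. Accepts an `annotation_set`, a
#' `puff_set` or a bare two-column matrix.
#'
#' @param x intervals to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  m <- if (inherits(x, c("annotation_set", "puff_set"))) x$intervals else
    as_interval_matrix(x)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write study report tables
#'
#' Serializes a named list of data frames both as a single JSON document
#' (`<stem>.json`, full double precision) and as one tab-separated file per
#' table (`<stem>_<name>.tsv`). Missing cells are rendered as `NA`.
#'
#' @param tables named list of data frames.
#' @param path output stem (without extension).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(tables, path) {
  if (!is.list(tables) || is.null(names(tables)) ||
      any(!nzchar(names(tables)))) {
    stop_config("tables must be a named list of data frames")
  }
  files <- character(0)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(tables, json_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = I(17), na = "null",
                       pretty = TRUE)
  files <- c(files, json_path)
  for (nm in names(tables)) {
    f <- paste0(path, "_", nm, ".tsv")
    utils::write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back the JSON half of a report written by [write_report()]
#'
#' @param path the stem passed to [write_report()].
#' @return Named list of data frames.
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lapply(out, as.data.frame)
}
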