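# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent condition classes so callers can distinguish user error kinds.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("puffstat_config_error", "error")))
}
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("puffstat_format_error", "error")))
}
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("puffstat_degenerate_error", "error")))
}

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(name, " must be a single finite number")
  }
  invisible(x)
}

# Force an integer to the nearest odd value >= 3.
force_odd <- function(n) {
  n <- as.integer(round(n))
  if (n %% 2L == 0L) n <- n + 1L
  max(n, 3L)
}

# Deterministic per-stream seed derivation from a master seed (keeps every
# derived seed a valid 32-bit integer).
derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stream) * 16807) %%
               2147483629) + 1L
}

# Extract samples from a recording or plain numeric vector.
as_samples <- function(x) {
  if (inherits(x, "recording")) x$samples else as.numeric(x)
}

# Intervals are 0-based half-open [start, end) sample-index pairs stored as a
# two-column integer matrix. Used by ground truth, annotations and puff sets.
as_interval_matrix <- function(intervals) {
  if (is.null(intervals) || (is.matrix(intervals) && nrow(intervals) == 0L) ||
      length(intervals) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  m <- if (is.matrix(intervals)) intervals else
    matrix(as.numeric(unlist(intervals)), ncol = 2L, byrow = TRUE)
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}

validate_intervals <- function(m, n_samples = NULL, what = "interval set") {
  m <- as_interval_matrix(m)
  if (nrow(m) == 0L) return(m)
  bad <- which(m[, 2L] <= m[, 1L] | m[, 1L] < 0L)
  if (!is.null(n_samples)) bad <- union(bad, which(m[, 2L] > n_samples))
  if (length(bad)) {
    stop_format(what, ": invalid rows (empty, negative or out of range): ",
                paste(sort(bad), collapse = ", "))
  }
  if (nrow(m) > 1L) {
    ord <- order(m[, 1L])
    if (any(ord != seq_len(nrow(m)))) {
      stop_format(what, ": rows are not sorted by start index")
    }
    overl <- which(m[-1L, 1L] < m[-nrow(m), 2L])
    if (length(overl)) {
      stop_format(what, ": overlapping rows: ",
                  paste(overl + 1L, collapse = ", "))
    }
  }
  m
}
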