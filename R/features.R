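#' Root-mean-square amplitude
#'
#' @param x numeric vector, [recording] or single puff.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  x <- as_samples(x)
  if (length(x) == 0L) stop_degenerate("rms of an empty vector is undefined")
  sqrt(mean(x^2))
}

# Fourier (band-limited) resampling of x to length L, scipy-resample style:
# truncate or zero-pad the spectrum symmetrically, splitting the Nyquist
# bin when present.
resample_fft <- function(x, L) {
  n <- length(x)
  if (L == n) return(x)
  X <- stats::fft(x)
  Y <- complex(L)
  m <- min(n, L)
  half <- (m + 1L) %/% 2L              # positive-frequency bins kept (excl. DC)
  Y[1L] <- X[1L]
  if (half > 1L) {
    Y[2:half] <- X[2:half]
    Y[(L - half + 2L):L] <- X[(n - half + 2L):n]
  }
  if (m %% 2L == 0L) {
    # shared Nyquist bin: split (upsampling) or fold (downsampling)
    nyq <- m %/% 2L + 1L
    if (L > n) {
      Y[nyq] <- X[nyq] / 2
      Y[L - m %/% 2L + 1L] <- X[nyq] / 2
    } else {
      Y[nyq] <- X[nyq] + X[n - m %/% 2L + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Resample a segment to length L by the requested method.
resample_to <- function(x, L, method = c("fourier", "linear")) {
  method <- match.arg(method)
  if (length(x) == L) return(as.numeric(x))
  if (method == "fourier") {
    resample_fft(as.numeric(x), L)
  } else {
    stats::approx(seq_along(x), x, n = L)$y
  }
}

#' Average puff curve
#'
#' Resamples every puff of a [puff_set()] to a common grid of `L` samples
#' (band-limited Fourier interpolation by default, linear as a fallback)
#' and averages pointwise. The result is the template against which
#' per-puff morphology variability is measured.
#'
#' @param puffs a [puff_set()] with at least one puff.
#' @param L grid length; default is the median puff length.
#' @param method `"fourier"` (band-limited) or `"linear"` interpolation.
#' @return An object of class `mean_puff` with fields `curve`, `L`,
#'   `n_source` and `fs`.
#' @export
mean_puff <- function(puffs, L = NULL, method = c("fourier", "linear")) {
  stopifnot(inherits(puffs, "puff_set"))
  method <- match.arg(method)
  if (length(puffs$segments) == 0L) {
    stop_degenerate("mean_puff needs at least one puff")
  }
  if (is.null(L)) L <- round(stats::median(lengths(puffs$segments)))
  L <- as.integer(L)
  if (L < 2L) stop_config("L must be at least 2")
  M <- vapply(puffs$segments, resample_to, numeric(L), L = L,
              method = method)
  structure(list(curve = rowMeans(M), L = L,
                 n_source = length(puffs$segments), fs = puffs$fs),
            class = "mean_puff")
}

#' @export
print.mean_puff <- function(x, ...) {
  cat(sprintf("<mean_puff> L=%d from %d puffs\n", x$L, x$n_source))
  invisible(x)
}

#' Normalized mean-square error between a puff and the mean curve
#'
#' Measures morphological deviation of one puff from the average puff:
#' `MSE = sum((p_i - m_i)^2) / (N * range^2)` where the puff is first
#' resampled to the mean curve's grid and `range = max(m) - min(m)` is the
#' peak-to-peak range of the mean curve. Normalizing by the squared range
#' makes the value dimensionless and invariant to common rescaling of puff
#' and mean curve. `normalization = "mean"` instead divides the raw sum of
#' squares by the mean-curve average (a non-scale-invariant variant kept
#' for comparability).
#'
#' @param puff numeric vector (one puff).
#' @param mean a [mean_puff()].
#' @param normalization `"range"` (default) or `"mean"`.
#' @param method resampling method, see [mean_puff()].
#' @return A single numeric value, 0 for a puff identical to the mean curve.
#' @export
puff_mse <- function(puff, mean, normalization = c("range", "mean"),
                     method = c("fourier", "linear")) {
  stopifnot(inherits(mean, "mean_puff"))
  normalization <- match.arg(normalization)
  p <- resample_to(as_samples(puff), mean$L, method = match.arg(method))
  m <- mean$curve
  ss <- sum((p - m)^2)
  if (normalization == "range") {
    rng <- max(m) - min(m)
    if (rng == 0) stop_degenerate("mean curve has zero range")
    ss / (mean$L * rng^2)
  } else {
    mbar <- base::mean(m)
    if (mbar == 0) stop_degenerate("mean curve has zero average")
    ss / mbar
  }
}

#' Welch-WOSA power spectral density
#'
#' Welch's overlapped segment averaging estimate: the signal is cut into
#' `seg_len`-sample segments with fractional `overlap`, each segment is
#' windowed (Hamming by default) and its modified periodogram computed; the
#' periodograms are averaged and scaled to a one-sided density in
#' units^2/Hz (so the integral over frequency approximates the signal
#' power).
#'
#' @param x numeric vector or [recording].
#' @param fs sampling rate in Hz (taken from the recording if omitted).
#' @param seg_len segment length in samples; defaults to
#'   `min(4096, length(x))`.
#' @param overlap fractional overlap in `[0, 1)`, default 0.5.
#' @param window `"hamming"`, `"hann"` or `"rect"`, or a numeric vector of
#'   length `seg_len`.
#' @return An object of class `spectral_summary` with fields `freqs`,
#'   `psd`, `fs`, `seg_len`, `n_segments`.
#' @export
welch_psd <- function(x, fs = NULL, seg_len = NULL, overlap = 0.5,
                      window = "hamming") {
  if (inherits(x, "recording")) {
    fs <- fs %||% x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop_config("fs is required for a plain numeric input")
  x <- as.numeric(x)
  n <- length(x)
  seg_len <- as.integer(seg_len %||% min(4096L, n))
  if (seg_len < 2L) stop_config("seg_len must be >= 2")
  if (seg_len > n) {
    stop_config("seg_len (", seg_len, ") exceeds signal length (", n, ")")
  }
  if (overlap < 0 || overlap >= 1) stop_config("overlap must be in [0, 1)")
  w <- if (is.numeric(window)) {
    if (length(window) != seg_len) stop_config("window vector length != seg_len")
    window
  } else switch(match.arg(window, c("hamming", "hann", "rect")),
    hamming = signal::hamming(seg_len),
    hann = signal::hanning(seg_len),
    rect = rep(1, seg_len))
  hop <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(nf)]
  }
  acc <- acc / length(starts)
  scale <- 1 / (fs * sum(w^2))
  psd <- acc * scale
  # one-sided: double everything except DC (and Nyquist when seg_len even)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (seg_len %% 2L == 0L) dbl[nf] <- 1
  psd <- psd * dbl
  structure(list(freqs = (seq_len(nf) - 1) * fs / seg_len, psd = psd,
                 fs = fs, seg_len = seg_len, n_segments = length(starts)),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d bins to %g Hz (%d segments of %d)\n",
              length(x$freqs), max(x$freqs), x$n_segments, x$seg_len))
  invisible(x)
}

#' Spectral moment parameters
#'
#' Power-weighted moments of a PSD restricted to a frequency band: the mean
#' frequency `f_mean = sum(f * P) / sum(P)`, the maximum-amplitude frequency
#' `f_max = argmax P`, and the spectral standard deviation
#' `spec_sd = sqrt(sum((f - f_mean)^2 * P) / sum(P))`, all in Hz.
#'
#' @param summary a `spectral_summary` (from [welch_psd()]) or a list with
#'   numeric `freqs` and `psd`.
#' @param band `c(f_lo, f_hi)` in Hz; default is the full grid.
#' @return Named list `f_mean`, `f_max`, `spec_sd` (Hz).
#' @export
spectral_params <- function(summary, band = NULL) {
  f <- summary$freqs
  P <- summary$psd
  if (length(f) != length(P)) stop_config("freqs and psd lengths differ")
  if (any(P < 0)) stop_config("psd must be nonnegative")
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] > band[2]) {
      stop_config("band must be c(f_lo, f_hi) with f_lo <= f_hi")
    }
    keep <- f >= band[1] & f <= band[2]
    f <- f[keep]; P <- P[keep]
  }
  if (length(f) == 0L || sum(P) == 0) {
    stop_degenerate("psd is empty or identically zero in the requested band")
  }
  f_mean <- sum(f * P) / sum(P)
  list(f_mean = f_mean,
       f_max = f[which.max(P)],
       spec_sd = sqrt(sum((f - f_mean)^2 * P) / sum(P)))
}
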