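# Surrogate-based time-frequency stationarity test.
#
# Stationarity over an observation horizon is identified with "the local
# spectra look like the global spectrum": a multitaper Hermite spectrogram
# provides low-variance local spectra, phase-randomized surrogates provide
# a stationarized null ensemble with the same power spectrum, and the
# variance over time of local-vs-global spectral divergences is compared
# between the observed signal (theta1) and the surrogates (theta0(j)).

#' Orthonormal Hermite window bank
#'
#' Returns the first `K` Hermite functions `H_{k-1}(t) * exp(-t^2/2)`
#' sampled on `Nh` points over `[-tmax, tmax]` and discretely
#' re-orthonormalized (QR), for use as multitaper spectrogram windows.
#' Window `k` has `k - 1` sign changes; the first window is the Gaussian.
#'
#' @param K number of windows (>= 1; typically 5-10).
#' @param Nh odd window length in samples; must exceed `4 * K` so the
#'   highest-order window is resolvable.
#' @param tmax half-width of the sampling interval in natural Hermite units.
#' @return An object of class `hermite_bank` with fields `K`, `Nh`,
#'   `windows` (an `Nh x K` matrix with orthonormal columns) and `t`.
#' @export
hermite_bank <- function(K, Nh, tmax = 6) {
  K <- as.integer(K); Nh <- as.integer(Nh)
  if (K < 1L) stop_config("K must be >= 1")
  if (Nh %% 2L == 0L) stop_config("Nh must be odd, got ", Nh)
  if (Nh <= 4L * K) stop_config("Nh must exceed 4*K (got Nh=", Nh,
                                ", K=", K, ")")
  t_ <- seq(-tmax, tmax, length.out = Nh)
  W <- matrix(0, Nh, K)
  g <- exp(-t_^2 / 2)
  Hkm2 <- rep(1, Nh)           # H_0
  W[, 1L] <- Hkm2 * g
  if (K >= 2L) {
    Hkm1 <- 2 * t_             # H_1
    W[, 2L] <- Hkm1 * g
    if (K >= 3L) {
      for (k in 3:K) {
        Hk <- 2 * t_ * Hkm1 - 2 * (k - 2) * Hkm2
        W[, k] <- Hk * g
        Hkm2 <- Hkm1; Hkm1 <- Hk
      }
    }
  }
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  qrW <- qr(W)
  Q <- qr.Q(qrW)[, seq_len(K), drop = FALSE]
  # QR may flip signs; align each orthonormal column with the raw window
  sgn <- sign(colSums(Q * W))
  Q <- sweep(Q, 2L, ifelse(sgn == 0, 1, sgn), "*")
  structure(list(K = K, Nh = Nh, windows = Q, t = t_),
            class = "hermite_bank")
}

#' @export
print.hermite_bank <- function(x, ...) {
  cat(sprintf("<hermite_bank> K=%d windows of %d samples\n", x$K, x$Nh))
  invisible(x)
}

# Slice x around center (1-based), zero-extending beyond the ends.
segment_at <- function(x, center, Nh) {
  hw <- (Nh - 1L) %/% 2L
  lo <- center - hw; hi <- center + hw
  seg <- numeric(Nh)
  src <- max(lo, 1L):min(hi, length(x))
  seg[src - lo + 1L] <- x[src]
  seg
}

#' Multitaper Hermite spectrogram
#'
#' Averages the `K` spectrograms obtained with each window of a
#' [hermite_bank()]: at each analysis time, the squared magnitude of the
#' windowed discrete Fourier transform, averaged over windows. Analysis
#' times are spaced by `stride` samples (default: half the window length,
#' i.e. half the equivalent analysis width) and kept inside the fully
#' supported range when possible; positions near the edges use zero
#' extension.
#'
#' @param x numeric vector or [recording]; must be at least `Nh` samples.
#' @param bank a [hermite_bank()].
#' @param stride spacing of analysis times in samples.
#' @param fs sampling rate (Hz) for the frequency grid; taken from the
#'   recording if available, else 1 (normalized frequency).
#' @param centers optional explicit 1-based analysis-time indices.
#' @return An object of class `mt_spectrogram`: `tn` (sample indices),
#'   `freqs` (one-sided grid), `S` (time-by-frequency matrix), `K`, `Nh`.
#' @export
mt_spectrogram <- function(x, bank, stride = NULL, fs = NULL,
                           centers = NULL) {
  stopifnot(inherits(bank, "hermite_bank"))
  if (inherits(x, "recording")) {
    fs <- fs %||% x$fs
    x <- x$samples
  }
  fs <- fs %||% 1
  x <- as.numeric(x)
  n <- length(x)
  Nh <- bank$Nh
  if (n < Nh) {
    stop_config("signal (", n, " samples) is shorter than the analysis ",
                "window (", Nh, " samples)")
  }
  stride <- as.integer(stride %||% max(1L, round(Nh / 2)))
  if (is.null(centers)) {
    hw <- (Nh - 1L) %/% 2L
    centers <- seq.int(hw + 1L, n - hw, by = stride)
    if (length(centers) == 0L) centers <- (n + 1L) %/% 2L
  }
  centers <- as.integer(centers)
  Seg <- vapply(centers, segment_at, numeric(Nh), x = x, Nh = Nh)
  nf <- (Nh + 1L) %/% 2L                 # one-sided bins (Nh odd: no Nyquist)
  S <- matrix(0, length(centers), nf)
  for (k in seq_len(bank$K)) {
    F_ <- stats::mvfft(Seg * bank$windows[, k])
    S <- S + t(Mod(F_[seq_len(nf), , drop = FALSE])^2)
  }
  structure(list(tn = centers, freqs = (seq_len(nf) - 1) * fs / Nh,
                 S = S / bank$K, K = bank$K, Nh = Nh, fs = fs),
            class = "mt_spectrogram")
}

#' @export
print.mt_spectrogram <- function(x, ...) {
  cat(sprintf("<mt_spectrogram> %d times x %d freqs (K=%d, Nh=%d)\n",
              nrow(x$S), ncol(x$S), x$K, x$Nh))
  invisible(x)
}

#' Phase-randomization surrogates
#'
#' Generates `J` stationarized copies of a signal: each surrogate keeps the
#' discrete Fourier modulus of `x` exactly but replaces the phase with
#' i.i.d. draws uniform on `[-pi, pi]` (Hermitian symmetry enforced; DC and
#' Nyquist bins kept at their original real values), destroying any
#' temporal structure while preserving the power spectrum.
#'
#' @param x numeric vector or [recording].
#' @param J number of surrogates.
#' @param seed master integer seed; surrogate `j` uses a derived stream, so
#'   individual surrogates are reproducible independently of `J`.
#' @return `length(x) x J` numeric matrix, one surrogate per column.
#' @export
make_surrogates <- function(x, J, seed = 1L) {
  x <- as_samples(x)
  n <- length(x)
  J <- as.integer(J)
  if (J < 1L) stop_config("J must be >= 1")
  X <- stats::fft(x)
  modulus <- Mod(X)
  # freely randomizable bins: everything except DC and (n even) Nyquist
  hi <- if (n %% 2L == 0L) n %/% 2L else (n + 1L) %/% 2L
  free <- if (hi >= 2L) seq.int(2L, hi) else integer(0)
  out <- matrix(0, n, J)
  for (j in seq_len(J)) {
    set.seed(derive_seed(seed, j))
    Xs <- complex(n)
    Xs[1L] <- X[1L]
    if (n %% 2L == 0L) Xs[n %/% 2L + 1L] <- X[n %/% 2L + 1L]
    if (length(free)) {
      ph <- stats::runif(length(free), -pi, pi)
      Xs[free] <- modulus[free] * exp(1i * ph)
      Xs[n + 2L - free] <- Conj(Xs[free])
    }
    out[, j] <- Re(stats::fft(Xs, inverse = TRUE)) / n
  }
  out
}

#' Divergence between two spectra
#'
#' The combined dissimilarity `k(G, H) = kKL(G~, H~) * (1 + kLSD(G, H))`
#' where `kKL` is the symmetric (Jeffreys) Kullback-Leibler divergence of
#' the unit-sum-normalized spectra, `sum((G~ - H~) * log(G~ / H~))`, and
#' `kLSD` is the mean absolute log-spectral deviation of the raw spectra.
#' Bins are floored at `eps * max(spectrum)` before logarithms.
#'
#' @param G,H nonnegative spectra on a common frequency grid, each with
#'   positive total mass.
#' @param eps relative flooring constant.
#' @return A single nonnegative number; 0 iff `G` and `H` are proportional
#'   up to the floor.
#' @export
spectral_distance <- function(G, H, eps = 1e-12) {
  G <- as.numeric(G); H <- as.numeric(H)
  if (length(G) != length(H)) stop_config("G and H must share a grid")
  if (any(G < 0) || any(H < 0)) stop_config("spectra must be nonnegative")
  if (sum(G) <= 0 || sum(H) <= 0) {
    stop_degenerate("spectral_distance needs positive total mass")
  }
  G <- pmax(G, eps * max(G))
  H <- pmax(H, eps * max(H))
  Gt <- G / sum(G); Ht <- H / sum(H)
  kl <- sum((Gt - Ht) * log(Gt / Ht))
  lsd <- mean(abs(log(G / H)))
  kl * (1 + lsd)
}

#' Local-versus-global spectral divergences
#'
#' The global spectrum is the time marginal (mean over analysis times) of
#' the spectrogram; `c_n` is the [spectral_distance()] between the local
#' spectrum at time `t_n` and that global spectrum. For a stationary
#' signal the `c_n` fluctuate little around a small value.
#'
#' @param spec an [mt_spectrogram()] with at least 2 analysis times.
#' @return Numeric vector `c` of length `nrow(spec$S)`.
#' @export
local_global_distances <- function(spec) {
  stopifnot(inherits(spec, "mt_spectrogram"))
  S <- spec$S
  if (nrow(S) < 2L) {
    stop_config("need at least 2 analysis times to compare local vs global")
  }
  if (max(S) == 0) return(numeric(nrow(S)))
  global <- colMeans(S)
  apply(S, 1L, spectral_distance, H = global)
}

#' Fluctuation statistic of the local-global divergences
#'
#' The empirical (population, 1/N) variance of the divergence sequence:
#' `theta = mean((c - mean(c))^2)`. This is the quantity compared between
#' the observed signal (theta1) and its surrogates (theta0).
#'
#' @param c numeric vector of local-global divergences (length >= 2).
#' @return A single nonnegative number.
#' @export
theta_statistic <- function(c) {
  c <- as.numeric(c)
  if (length(c) < 2L) stop_config("theta_statistic needs at least 2 values")
  mean((c - mean(c))^2)
}

# Gamma MLE on mean-scaled data with method-of-moments start; NULL on
# failure so the caller can fall back to the empirical quantile.
fit_gamma_null <- function(theta0) {
  mu <- mean(theta0)
  if (!is.finite(mu) || mu <= 0 || any(theta0 <= 0)) return(NULL)
  z <- theta0 / mu
  v <- stats::var(z)
  if (!is.finite(v) || v <= 0) return(NULL)
  start <- list(shape = 1 / v, rate = 1 / v)
  fit <- tryCatch(
    suppressWarnings(fitdistrplus::fitdist(z, "gamma", start = start)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$estimate))) return(NULL)
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  list(shape = shape, scale = mu / rate)
}

# theta for one signal at a fixed bank/stride.
theta_of_signal <- function(x, bank, stride) {
  spec <- mt_spectrogram(x, bank, stride = stride)
  theta_statistic(local_global_distances(spec))
}

#' Surrogate-based stationarity test with INS
#'
#' Runs the full test on one signal: a multitaper Hermite spectrogram with
#' window length `Nh = odd(round(win_frac * length(x)))`; `theta1`, the
#' variance over time of the local-vs-global spectral divergences of `x`;
#' the same statistic `theta0(j)` for `J` phase-randomization surrogates; a
#' gamma distribution fitted to the `theta0` sample (maximum likelihood,
#' method-of-moments start; empirical quantile fallback with a warning);
#' the decision threshold `gamma` as the `1 - alpha` quantile of that null
#' fit; and the index of non-stationarity
#' `INS = sqrt(theta1 / mean(theta0))`, about 1 for stationary signals,
#' with `INS_threshold = sqrt(threshold / mean(theta0))`. Setting
#' `sqrt_ins = FALSE` reports the plain ratio `theta1 / mean(theta0)`
#' instead (and the matching threshold ratio).
#'
#' @param x numeric vector or [recording].
#' @param K number of Hermite windows.
#' @param win_frac analysis-window length as a fraction of the signal
#'   length (typical values 0.03-0.075).
#' @param J number of surrogates (the reference study value is 5000; 50
#'   already gives stable decisions).
#' @param alpha test level.
#' @param seed master seed for the surrogate phases.
#' @param sqrt_ins report the square-root INS convention (default) or the
#'   plain ratio.
#' @param stride analysis-time spacing in samples (default `Nh / 2`).
#' @return An object of class `tf_stationarity`: `theta1`, `theta0`
#'   (length-`J` vector), `gamma_shape`, `gamma_scale`, `threshold`,
#'   `decision`, `INS`, `INS_threshold`, plus the analysis parameters.
#' @export
test_stationarity <- function(x, K = 5, win_frac = 0.05, J = 5000,
                              alpha = 0.05, seed = 1L, sqrt_ins = TRUE,
                              stride = NULL) {
  x <- as_samples(x)
  n <- length(x)
  Nh <- force_odd(round(win_frac * n))
  if (Nh <= 4L * K) {
    stop_config("window of ", Nh, " samples (win_frac=", win_frac,
                " of n=", n, ") is too short for K=", K,
                " Hermite windows (need Nh > 4K)")
  }
  if (Nh > n) {
    stop_config("window of ", Nh, " samples exceeds the signal length ", n)
  }
  bank <- hermite_bank(K, Nh)
  stride <- as.integer(stride %||% max(1L, round(Nh / 2)))
  theta1 <- theta_of_signal(x, bank, stride)
  surr <- make_surrogates(x, J, seed = seed)
  theta0 <- apply(surr, 2L, theta_of_signal, bank = bank, stride = stride)
  m0 <- mean(theta0)
  fit <- fit_gamma_null(theta0)
  if (is.null(fit)) {
    warning("gamma fit to the surrogate null failed; using the empirical ",
            "quantile", call. = FALSE)
    threshold <- unname(stats::quantile(theta0, 1 - alpha))
    shape <- NA_real_; scale <- NA_real_
  } else {
    shape <- fit$shape; scale <- fit$scale
    threshold <- stats::qgamma(1 - alpha, shape = shape, scale = scale)
  }
  ratio <- function(v) if (sqrt_ins) sqrt(v / m0) else v / m0
  structure(
    list(theta1 = theta1, theta0 = theta0, gamma_shape = shape,
         gamma_scale = scale, threshold = threshold,
         decision = if (theta1 > threshold) "non-stationary" else
           "stationary",
         INS = ratio(theta1), INS_threshold = ratio(threshold),
         J = J, K = K, Nh = Nh, win_frac = win_frac, alpha = alpha,
         stride = stride, seed = as.integer(seed), sqrt_ins = sqrt_ins),
    class = "tf_stationarity"
  )
}

#' @export
print.tf_stationarity <- function(x, ...) {
  cat(sprintf(paste0("Time-frequency stationarity test (K=%d, Nh=%d, ",
                     "J=%d, alpha=%g)\n"), x$K, x$Nh, x$J, x$alpha))
  cat(sprintf("  theta1 = %.4g, threshold = %.4g -> %s\n",
              x$theta1, x$threshold, x$decision))
  cat(sprintf("  INS = %.4f (threshold %.4f)\n", x$INS, x$INS_threshold))
  invisible(x)
}

#' INS as a function of analysis-window size
#'
#' Reruns [test_stationarity()] for each window fraction in
#' `win_frac_list` with a common master seed, tracking how the index of
#' non-stationarity and its threshold evolve with the local-analysis
#' horizon.
#'
#' @inheritParams test_stationarity
#' @param win_frac_list numeric vector of window fractions.
#' @return A data frame with columns `win_frac`, `INS`, `INS_threshold`,
#'   `theta1`, `threshold`, `decision`.
#' @export
ins_curve <- function(x, K = 5, win_frac_list = c(0.03, 0.04, 0.05, 0.07,
                                                  0.075),
                      J = 5000, alpha = 0.05, seed = 1L, sqrt_ins = TRUE) {
  rows <- lapply(win_frac_list, function(wf) {
    r <- test_stationarity(x, K = K, win_frac = wf, J = J, alpha = alpha,
                           seed = seed, sqrt_ins = sqrt_ins)
    data.frame(win_frac = wf, INS = r$INS, INS_threshold = r$INS_threshold,
               theta1 = r$theta1, threshold = r$threshold,
               decision = r$decision, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(win_frac = numeric(0), INS = numeric(0),
                      INS_threshold = numeric(0), theta1 = numeric(0),
                      threshold = numeric(0), decision = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Diagnostic plot of the surrogate null and the observed statistic
#'
#' Histogram of the surrogate `theta0` sample with the fitted gamma density
#' overlaid and the observed `theta1` marked; for a stationary signal the
#' marker falls inside the bulk of the null, for a non-stationary one far
#' beyond its upper quantile.
#'
#' @param result a `tf_stationarity` from [test_stationarity()].
#' @param ... passed to [graphics::hist()].
#' @return `result`, invisibly.
#' @export
plot_theta_null <- function(result, ...) {
  stopifnot(inherits(result, "tf_stationarity"))
  xmax <- max(result$theta0, result$theta1, result$threshold)
  h <- graphics::hist(result$theta0, freq = FALSE,
                      xlim = c(0, 1.05 * xmax),
                      main = "Surrogate null of theta",
                      xlab = "theta", ...)
  if (is.finite(result$gamma_shape)) {
    xx <- seq(0, 1.05 * xmax, length.out = 400)
    graphics::lines(xx, stats::dgamma(xx, shape = result$gamma_shape,
                                      scale = result$gamma_scale))
  }
  graphics::abline(v = result$threshold, lty = 2)
  graphics::abline(v = result$theta1, col = "magenta", lwd = 2)
  invisible(result)
}
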