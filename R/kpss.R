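# KPSS stationarity test: null hypothesis is (level- or trend-) stationarity.
# The statistic is T^-2 * sum_t S_t^2 / s^2, where S_t are partial sums of
# the residuals from regressing the series on a constant (level variant,
# eta_mu) or on a constant plus linear trend (trend variant, eta_tau), and
# s^2 is the Bartlett-weighted long-run variance of the residuals.

# Asymptotic critical values (Kwiatkowski et al.), by variant and alpha.
kpss_critical_table <- function(variant) {
  switch(variant,
    level = c("0.1" = 0.347, "0.05" = 0.463, "0.025" = 0.574, "0.01" = 0.739),
    trend = c("0.1" = 0.119, "0.05" = 0.146, "0.025" = 0.176, "0.01" = 0.216))
}

kpss_residuals <- function(y, variant) {
  if (variant == "level") {
    y - mean(y)
  } else {
    t_ <- seq_along(y)
    stats::.lm.fit(cbind(1, t_), y)$residuals
  }
}

# Bartlett-kernel long-run variance with bandwidth `nlags`.
long_run_variance <- function(e, nlags) {
  T_ <- length(e)
  s2 <- sum(e^2) / T_
  if (nlags > 0L) {
    for (l in seq_len(nlags)) {
      w <- 1 - l / (nlags + 1)
      s2 <- s2 + (2 / T_) * w * sum(e[(l + 1):T_] * e[1:(T_ - l)])
    }
  }
  s2
}

#' KPSS stationarity statistic
#'
#' Computes the KPSS statistic for the null hypothesis that a series is
#' stationary in level (`variant = "level"`) or around a deterministic
#' linear trend (`variant = "trend"`). Large values indicate that the
#' partial sums of the regression residuals wander like a random walk,
#' i.e. non-stationarity.
#'
#' @param y numeric vector or [recording] (length >= 10).
#' @param variant `"trend"` (default; matches the 0.146 decision threshold
#'   used for the global recordings) or `"level"`.
#' @param nlags long-run-variance bandwidth; default is the Newey-West rule
#'   `floor(4 * (T/100)^0.25)`. Use 0 for the no-correction statistic.
#' @return An object of class `kpss_result` (fields `statistic`, `variant`,
#'   `nlags`, `n`; decision fields filled by [kpss_decision()]).
#' @export
kpss_statistic <- function(y, variant = c("trend", "level"), nlags = NULL) {
  variant <- match.arg(variant)
  y <- as_samples(y)
  T_ <- length(y)
  if (T_ < 10L) stop_config("kpss_statistic needs at least 10 samples")
  nlags <- as.integer(nlags %||% floor(4 * (T_ / 100)^0.25))
  if (nlags < 0L || nlags >= T_) stop_config("nlags must be in [0, T)")
  e <- kpss_residuals(y, variant)
  s2 <- long_run_variance(e, nlags)
  if (s2 <= 0 || !is.finite(s2)) {
    stop_degenerate("long-run variance is zero; statistic undefined")
  }
  S <- cumsum(e)
  structure(list(statistic = sum(S^2) / (T_^2 * s2), variant = variant,
                 nlags = nlags, n = T_, critical_value = NA_real_,
                 alpha = NA_real_, decision = NA_character_),
            class = "kpss_result")
}

#' KPSS decision against a critical value
#'
#' Declares the series stationary iff `statistic < critical_value`
#' (strictly; a statistic exactly at the threshold is called
#' non-stationary). Critical values default to the asymptotic table
#' (trend variant at alpha = 0.05: 0.146); pass `critical_value` to use a
#' Monte-Carlo estimate from [kpss_critical_value_mc()].
#'
#' @param result a `kpss_result` from [kpss_statistic()].
#' @param alpha significance level; tabulated values exist for 0.10, 0.05,
#'   0.025 and 0.01.
#' @param critical_value optional explicit threshold overriding the table.
#' @return The `kpss_result` with `critical_value`, `alpha` and `decision`
#'   (`"stationary"` / `"non-stationary"`) filled in.
#' @export
kpss_decision <- function(result, alpha = 0.05, critical_value = NULL) {
  stopifnot(inherits(result, "kpss_result"))
  if (is.null(critical_value)) {
    tab <- kpss_critical_table(result$variant)
    key <- format(alpha)
    if (!key %in% names(tab)) {
      stop_config("no tabulated critical value for alpha=", alpha,
                  "; supply critical_value (e.g. from ",
                  "kpss_critical_value_mc)")
    }
    critical_value <- unname(tab[key])
  }
  result$critical_value <- critical_value
  result$alpha <- alpha
  result$decision <- if (result$statistic < critical_value) "stationary"
                     else "non-stationary"
  result
}

#' One-call KPSS test
#'
#' @inheritParams kpss_statistic
#' @inheritParams kpss_decision
#' @return A decided `kpss_result`.
#' @export
kpss_test <- function(y, variant = c("trend", "level"), nlags = NULL,
                      alpha = 0.05, critical_value = NULL) {
  kpss_decision(kpss_statistic(y, variant, nlags), alpha, critical_value)
}

#' @export
print.kpss_result <- function(x, ...) {
  cat(sprintf("KPSS (%s): statistic = %.4f (T = %d, nlags = %d)\n",
              x$variant, x$statistic, x$n, x$nlags))
  if (!is.na(x$decision)) {
    cat(sprintf("  critical value %.4f at alpha = %g -> %s\n",
                x$critical_value, x$alpha, x$decision))
  }
  invisible(x)
}

# Vectorized nlags = 0 statistic over the columns of a matrix of series;
# used by the Monte-Carlo machinery. Must agree column-by-column with
# kpss_statistic(, nlags = 0).
kpss_stat0_matrix <- function(Y, variant) {
  T_ <- nrow(Y)
  E <- if (variant == "level") {
    sweep(Y, 2L, colMeans(Y))
  } else {
    X <- cbind(1, seq_len(T_))
    Q <- qr.Q(qr(X))
    Y - Q %*% crossprod(Q, Y)
  }
  S <- apply(E, 2L, cumsum)
  colSums(S^2) / (T_^2) / (colSums(E^2) / T_)
}

#' Monte-Carlo critical value for the KPSS statistic
#'
#' Simulates `reps` independent Gaussian white-noise series of length `T`
#' under the stationarity null, computes the KPSS statistic of each with
#' `nlags = 0` (white noise needs no long-run-variance correction), and
#' returns the empirical `1 - alpha` quantile. With the trend variant,
#' `T = 2000` and large `reps` this reproduces the classical 0.146
#' threshold at `alpha = 0.05`.
#'
#' @param variant `"trend"` or `"level"`.
#' @param alpha significance level.
#' @param T series length.
#' @param reps number of null replicates (>= 1000).
#' @param seed integer seed.
#' @param chunk internal column-block size for memory control.
#' @return The empirical critical value (single number).
#' @export
kpss_critical_value_mc <- function(variant = c("trend", "level"),
                                   alpha = 0.05, T = 2000, reps = 50000,
                                   seed = 1L, chunk = 200L) {
  variant <- match.arg(variant)
  if (reps < 1000) stop_config("reps must be >= 1000 for a stable quantile")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  stats <- kpss_null_sample(variant, T, reps, seed, chunk)
  unname(stats::quantile(stats, 1 - alpha))
}

# Draw `reps` null statistics (white noise, nlags = 0). Exposed internally
# so the type-I-error check can reuse the same sampler.
kpss_null_sample <- function(variant, T, reps, seed, chunk = 200L) {
  set.seed(as.integer(seed))
  out <- numeric(reps)
  done <- 0L
  while (done < reps) {
    m <- min(chunk, reps - done)
    Y <- matrix(stats::rnorm(T * m), nrow = T)
    out[(done + 1L):(done + m)] <- kpss_stat0_matrix(Y, variant)
    done <- done + m
  }
  out
}
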