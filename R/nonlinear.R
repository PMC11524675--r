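## Complexity features: sample entropy, multiscale entropy, detrended
## fluctuation analysis.

#' Sample entropy
#'
#' The negative natural logarithm of the conditional probability that two
#' series segments matching for `m` points (Chebyshev distance strictly below
#' the tolerance, self-matches excluded) also match for `m + 1` points:
#' `-ln(psi_{m+1} / psi_m)`. The tolerance is `r_factor` times the series
#' standard deviation, so the measure is invariant to affine transforms of
#' the input.
#'
#' @param x Numeric series, length > m + 1.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a multiple of `sd(x)` (default 0.2).
#' @param r Absolute tolerance; overrides `r_factor` when given (used by
#'   [mse()], which keeps the tolerance fixed across scales).
#' @return Non-negative scalar in nats; `NA` with a warning if no template
#'   pair matches at length m + 1.
#' @export
sampen <- function(x, m = 2, r_factor = 0.2, r = NULL) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("series too short: need length > m + 1")
  if (is.null(r)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance series: tolerance undefined")
    r <- r_factor * s
  }
  if (!is.finite(r) || r <= 0) stop("tolerance must be positive")
  cnt <- sampen_counts(x, as.integer(m), r)
  if (cnt$matches_m == 0 || cnt$matches_m1 == 0) {
    warning("no template matches at m + 1; sample entropy undefined")
    return(NA_real_)
  }
  -log(cnt$matches_m1 / cnt$matches_m)
}

#' Coarse-grain a series
#'
#' Non-overlapping block means of `scale` consecutive points (the multiscale
#' coarse-graining); output length `floor(length(x)/scale)`.
#'
#' @param x Numeric series.
#' @param scale Block size (>= 1).
#' @return Coarse-grained series.
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  stopifnot(scale >= 1)
  n <- length(x) %/% scale
  if (n == 0) return(numeric(0))
  colMeans(matrix(x[seq_len(n * scale)], scale, n))
}

#' Multiscale entropy
#'
#' Sample entropy of the coarse-grained series at scales `1..max_scale`,
#' summed over scales. The tolerance is fixed once at `r_factor` times the
#' SD of the original (scale-1) series, so the entropy decline caused by
#' coarse-grain averaging is part of the measure (the standard multiscale
#' convention). Scales whose coarse series is too short or degenerate are
#' skipped with a warning and appear as `NA` in the per-scale curve.
#'
#' @inheritParams sampen
#' @param max_scale Maximum coarse-graining factor (default 10).
#' @return Scalar sum over scales (nats), with the per-scale curve attached
#'   as attribute `"scales"`.
#' @export
mse <- function(x, m = 2, r_factor = 0.2, max_scale = 10) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance series: tolerance undefined")
  r_abs <- r_factor * s
  curve <- rep(NA_real_, max_scale)
  for (tau in seq_len(max_scale)) {
    xc <- coarse_grain(x, tau)
    val <- tryCatch(suppressWarnings(sampen(xc, m, r = r_abs)),
                    error = function(e) NA_real_)
    curve[tau] <- val
  }
  if (anyNA(curve)) {
    warning("sample entropy undefined at scale(s) ",
            paste(which(is.na(curve)), collapse = ", "), "; skipped in the sum")
  }
  structure(sum(curve, na.rm = TRUE), scales = curve)
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-removed series, splits the profile into non-overlapping
#' windows of each length `n`, removes the least-squares line in each window,
#' and pools the residuals into the fluctuation function `F(n)` (RMS). The
#' scaling exponent alpha is the least-squares slope of `log F(n)` against
#' `log n`. White noise gives alpha ~ 0.5, 1/f noise ~ 1, a random walk ~ 1.5.
#'
#' @param x Numeric series.
#' @param window_lengths Increasing window lengths (samples); entries above
#'   `length(x)/4` are dropped.
#' @return Scalar exponent alpha, with `data.frame(n, F)` attached as
#'   attribute `"fluctuation"`.
#' @export
dfa <- function(x, window_lengths = c(4, 6, 9, 13, 19, 28, 42, 63, 94, 141, 211)) {
  x <- as.numeric(x)
  N <- length(x)
  ns <- as.integer(window_lengths)
  ns <- ns[ns >= 4 & ns <= N / 4]
  if (length(ns) < 3) {
    stop("fewer than 3 usable window lengths (need n in [4, N/4], N = ", N, ")")
  }
  y <- cumsum(x - mean(x))
  Fn <- vapply(ns, function(n) {
    k <- N %/% n
    prof <- matrix(y[seq_len(k * n)], n, k)
    t_loc <- seq_len(n)
    X <- cbind(1, t_loc)
    beta <- solve(crossprod(X), crossprod(X, prof))
    res <- prof - X %*% beta
    sqrt(mean(res^2))
  }, 0)
  fit <- stats::lm.fit(cbind(1, log(ns)), log(Fn))
  structure(unname(fit$coefficients[2]),
            fluctuation = data.frame(n = ns, F = Fn))
}
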