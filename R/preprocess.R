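## Preprocessing: detrend -> band-pass -> ICA artifact removal -> windowing.
## The stage order is fixed; each stage takes and returns an eeg_recording so
## stages can also be used in isolation.

#' Remove per-channel linear trends
#'
#' Subtracts the least-squares line from every channel, removing means,
#' offsets and slow linear drifts. Idempotent.
#'
#' @param rec An `eeg_recording`.
#' @return The detrended recording.
#' @export
detrend_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$signal)
  if (n < 2) stop("detrending needs at least 2 samples")
  t <- seq_len(n)
  X <- cbind(1, t)
  # one normal-equations solve for all channels at once
  beta <- solve(crossprod(X), crossprod(X, t(rec$signal)))
  rec$signal <- rec$signal - t(X %*% beta)
  rec
}

.butter_sos <- function(order, w, type) {
  flt <- signal::butter(order, w, type = type)
  flt
}

# single-pass IIR filter started in steady state for the first sample, so a
# constant input produces no start-up transient
.lfilter_ss <- function(flt, x) {
  b <- flt$b; a <- flt$a
  gdc <- sum(b) / sum(a)
  y0 <- x[1] * gdc
  as.numeric(signal::filter(flt, x, init.x = rep(x[1], length(b) - 1),
                            init.y = rep(y0, length(a) - 1)))
}

# zero-phase forward-backward filtering with odd-reflection end padding and
# steady-state initialization (scipy-style filtfilt)
.filtfilt_pad <- function(flt, x) {
  n <- length(x)
  pad <- min(n - 1, max(3 * (length(flt$a) + length(flt$b)), 100))
  head_ext <- 2 * x[1] - x[(pad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(head_ext, x, tail_ext)
  y <- .lfilter_ss(flt, xe)
  y <- rev(.lfilter_ss(flt, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase band-pass filter
#'
#' Butterworth high-pass and low-pass filters (default order 4 each) applied
#' in cascade, each forward--backward (`filtfilt`), so the net filter has zero
#' phase and squared magnitude response. Defaults implement the 0.5--50 Hz
#' analysis band.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Corner frequencies in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order of each cascade element.
#' @return The filtered recording.
#' @export
bandpass_recording <- function(rec, low = 0.5, high = 50, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2 (got low=", low, ", high=", high,
         ", fs=", fs, ")")
  }
  hp <- .butter_sos(order, low / (fs / 2), "high")
  lp <- .butter_sos(order, high / (fs / 2), "low")
  for (ch in seq_len(nrow(rec$signal))) {
    x <- .filtfilt_pad(hp, rec$signal[ch, ])
    rec$signal[ch, ] <- .filtfilt_pad(lp, x)
  }
  rec
}

#' FastICA decomposition
#'
#' Symmetric FastICA with the logcosh contrast on PCA-whitened data.
#' Deterministic given `seed`.
#'
#' @param X Numeric matrix, channels x samples.
#' @param n_components Number of components to extract (<= nrow(X)).
#' @param seed Integer seed for the random initial rotation.
#' @param max_iter,tol Iteration controls.
#' @return List with `S` (components x samples source estimates), `A`
#'   (channels x components mixing matrix), `W` (unmixing), `center`
#'   (channel means): `X ~ A %*% S + center`.
#' @export
fastica <- function(X, n_components = nrow(X), seed = 1L,
                    max_iter = 400, tol = 1e-7) {
  n_ch <- nrow(X)
  if (n_components > n_ch) {
    stop("n_components (", n_components, ") exceeds channel count (", n_ch, ")")
  }
  center <- rowMeans(X)
  Xc <- X - center
  n <- ncol(Xc)
  cv <- tcrossprod(Xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  d <- pmax(eg$values[keep], .Machine$double.eps)
  K <- diag(1 / sqrt(d), n_components) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc                      # whitened: cov(Z) = I

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  W <- matrix(stats::rnorm(n_components^2), n_components)
  sym_decorrelate <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(Gp), n_components) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  # S = (W K) Xc; with orthogonal W, Xc ~ E D^{1/2} W' S
  A <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(d), n_components) %*% t(W)   # channels x components
  list(S = S, A = A, W = W %*% K, center = center)
}

#' Remove ICA components from a recording
#'
#' Decomposes the signal with [fastica()], zeroes the rejected components and
#' reconstructs. Components are rejected either by explicit index (`reject`,
#' for visually identified artifacts on real data) or automatically, by
#' correlating each component time course with one or more reference artifact
#' time courses (`templates`) and rejecting components with absolute
#' correlation above `template_threshold`.
#'
#' @param rec An `eeg_recording`.
#' @param n_components Number of ICA components (default 40, capped at the
#'   channel count).
#' @param reject Integer vector of component indices to remove.
#' @param templates Optional numeric vector or samples x k matrix of reference
#'   artifact time courses (e.g. a known blink source).
#' @param template_threshold Absolute-correlation threshold for automatic
#'   rejection (default 0.5).
#' @param seed Seed passed to [fastica()].
#' @return The cleaned recording, with attributes `rejected_components`
#'   (indices removed) and `n_components`.
#' @export
ica_clean <- function(rec, n_components = 40, reject = integer(0),
                      templates = NULL, template_threshold = 0.5, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_components <- min(n_components, nrow(rec$signal))
  dec <- fastica(rec$signal, n_components = n_components, seed = seed)
  reject <- as.integer(reject)
  if (length(reject) && (min(reject) < 1 || max(reject) > n_components)) {
    stop("reject indices out of range 1..", n_components)
  }
  if (!is.null(templates)) {
    tm <- as.matrix(templates)
    if (nrow(tm) != ncol(rec$signal)) {
      stop("templates must have one row per sample")
    }
    cors <- abs(stats::cor(t(dec$S), tm))
    auto <- which(apply(cors, 1, max) > template_threshold)
    reject <- sort(unique(c(reject, auto)))
  }
  S <- dec$S
  if (length(reject)) S[reject, ] <- 0
  rec$signal <- dec$A %*% S + dec$center
  rownames(rec$signal) <- rec$channel_labels
  attr(rec, "rejected_components") <- reject
  attr(rec, "n_components") <- n_components
  rec
}

#' Cut a recording into non-overlapping windows
#'
#' Consecutive windows of exactly `window_length * fs` samples; a trailing
#' partial window is discarded so that every window is directly comparable
#' for the entropy and fluctuation measures.
#'
#' @param rec An `eeg_recording`.
#' @param window_length Window length in seconds (default 2).
#' @return List of `eeg_window` objects (possibly empty, with a warning, if
#'   the recording is shorter than one window).
#' @export
segment_recording <- function(rec, window_length = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  spw <- round(window_length * rec$fs)
  n_win <- ncol(rec$signal) %/% spw
  if (n_win == 0) {
    warning("recording shorter than one window (", recording_duration(rec),
            " s < ", window_length, " s); returning no windows")
    return(list())
  }
  lapply(seq_len(n_win), function(k) {
    sub <- rec
    sub$signal <- rec$signal[, ((k - 1) * spw + 1):(k * spw), drop = FALSE]
    as_window(sub, k)
  })
}

#' Run the full preprocessing chain
#'
#' detrend -> 0.5--50 Hz band-pass -> optional ICA cleanup -> windowing.
#'
#' @param rec An `eeg_recording`.
#' @param config A [run_config()].
#' @param ica Whether to run ICA cleanup (default: only when `templates` or
#'   `reject` is given).
#' @param reject,templates Passed to [ica_clean()].
#' @return List of `eeg_window` objects; the cleaned continuous recording is
#'   attached as attribute `"recording"` (used for per-recording coherence).
#' @export
preprocess_recording <- function(rec, config = run_config(),
                                 ica = !is.null(templates) || length(reject) > 0,
                                 reject = integer(0), templates = NULL) {
  edges <- range(unlist(config$band_edges))
  rec <- detrend_recording(rec)
  rec <- bandpass_recording(rec, low = edges[1], high = edges[2])
  if (ica) {
    rec <- ica_clean(rec, n_components = config$ica_components,
                     reject = reject, templates = templates,
                     seed = config$seed)
  }
  wins <- segment_recording(rec, config$window_length)
  attr(wins, "recording") <- rec
  wins
}
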