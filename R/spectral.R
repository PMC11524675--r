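## Spectral feature families: discrete-wavelet band powers, relative power,
## alpha interhemispheric asymmetry, and Welch magnitude-squared coherence.

# Daubechies orthonormal scaling filters (natural order h_0..h_{L-1})
.daub_filters <- list(
  db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
          -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728),
  db8 = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
          0.58535468365420673, -0.015829105256349306, -0.28401554296154691,
          0.00047248457391328279, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
          -0.0048703529934515741, -0.00039174037337694705,
          0.00067544940645056933, -0.00011747678412476953)
)

# one level of the periodized orthogonal DWT; returns approximation and detail
.dwt_step <- function(x, h) {
  n <- length(x)
  half <- n / 2
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)    # wavelet filter
  idx <- outer(2 * (seq_len(half) - 1), seq_len(L) - 1, `+`) %% n + 1
  xm <- matrix(x[idx], half, L)
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

#' Periodized Daubechies wavelet decomposition
#'
#' Orthonormal pyramid transform; total coefficient energy equals signal
#' energy exactly (Parseval). The input is zero-padded to the next multiple
#' of `2^levels`. The default filter is db8, whose sharper band transitions
#' keep a mid-band sinusoid's energy concentrated in a single level; db4 is
#' also available.
#'
#' @param x Numeric series.
#' @param levels Number of decomposition levels.
#' @param filter `"db8"` (default) or `"db4"`.
#' @return List with `details` (list of detail coefficient vectors, level 1 =
#'   finest) and `approx` (final approximation coefficients).
#' @export
dwt_daub <- function(x, levels, filter = c("db8", "db4")) {
  filter <- match.arg(filter)
  h <- .daub_filters[[filter]]
  n0 <- length(x)
  block <- 2^levels
  n <- ceiling(n0 / block) * block
  if (n > n0) x <- c(x, numeric(n - n0))
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- .dwt_step(a, h)
    details[[j]] <- st$d
    a <- st$a
  }
  list(details = details, approx = a)
}

# number of levels so the final approximation tops out near 2 Hz
.dwt_levels <- function(fs) max(3L, round(log2(fs / 4)))

# map each detail level (and the approximation) to the band with the largest
# log-frequency overlap; levels above the highest band edge stay unassigned
.band_level_map <- function(fs, band_edges, levels) {
  ranges <- lapply(seq_len(levels), function(j) c(fs / 2^(j + 1), fs / 2^j))
  ranges <- c(ranges, list(c(1e-3, fs / 2^(levels + 1))))  # approximation
  assign_one <- function(rg) {
    ov <- vapply(band_edges, function(be) {
      lo <- max(rg[1], be[1]); hi <- min(rg[2], be[2])
      if (hi > lo) log(hi / lo) else 0
    }, 0)
    if (all(ov == 0)) NA_integer_ else which.max(ov)
  }
  vapply(ranges, assign_one, 1L)
}

#' Wavelet band powers of a window
#'
#' Decomposes each channel with the periodized db8 transform and sums squared
#' coefficients over the decomposition levels mapped to each frequency band
#' (at 500 Hz with the default bands: gamma ~ D3, beta ~ D4, alpha ~ D5,
#' theta ~ D6, delta ~ D7 + A7).
#'
#' @param w An `eeg_window` (or any `eeg_recording`).
#' @param band_edges Named list of band edges in Hz (default: delta, theta,
#'   alpha, beta, gamma covering 0.5--50 Hz).
#' @return Numeric matrix channels x bands of band powers (coefficient
#'   energy), with dimnames.
#' @export
wavelet_band_decompose <- function(w, band_edges = .default_bands()) {
  stopifnot(inherits(w, "eeg_recording"))
  fs <- w$fs
  if (fs / 2 < max(vapply(band_edges, `[`, 0, 2))) {
    stop("sampling rate ", fs, " Hz too low to resolve the highest band")
  }
  levels <- .dwt_levels(fs)
  map <- .band_level_map(fs, band_edges, levels)
  out <- matrix(0, nrow(w$signal), length(band_edges),
                dimnames = list(w$channel_labels, names(band_edges)))
  for (ch in seq_len(nrow(w$signal))) {
    dec <- dwt_daub(w$signal[ch, ], levels)
    en <- c(vapply(dec$details, function(d) sum(d^2), 0), sum(dec$approx^2))
    for (b in seq_along(band_edges)) {
      out[ch, b] <- sum(en[which(map == b)])
    }
  }
  out
}

#' Relative band power
#'
#' Each band's power divided by the channel's total power across all bands,
#' so per-channel values sum to 1.
#'
#' @param band_power Channels x bands matrix of non-negative band powers
#'   (from [wavelet_band_decompose()]).
#' @return Matrix of the same shape with rows summing to 1.
#' @export
relative_power <- function(band_power) {
  tot <- rowSums(band_power)
  zero <- tot <= 0
  if (any(zero)) {
    stop("all-zero band power for channel(s): ",
         paste(rownames(band_power)[zero], collapse = ", "))
  }
  band_power / tot
}

#' Interhemispheric asymmetry index
#'
#' `(R - L)/(R + L)` for non-negative homologous right/left powers; in
#' [-1, 1], antisymmetric under exchanging R and L.
#'
#' @param power_right,power_left Non-negative powers (vectorized).
#' @return Asymmetry indices.
#' @export
asymmetry_index <- function(power_right, power_left) {
  if (any(power_right < 0) || any(power_left < 0)) {
    stop("powers must be non-negative")
  }
  s <- power_right + power_left
  if (any(s == 0)) stop("R + L = 0: asymmetry undefined")
  (power_right - power_left) / s
}

#' Alpha asymmetry over a montage's pair inventory
#'
#' @param band_power Channels x bands power matrix (dimnames required).
#' @param montage An `eeg_montage`.
#' @param band Band name (default `"alpha"`).
#' @return Named vector, one asymmetry index per montage pair
#'   (`asym:alpha:F3-F4` naming).
#' @export
alpha_asymmetry <- function(band_power, montage, band = "alpha") {
  pr <- montage$asymmetry_pairs
  missing <- setdiff(unique(c(pr$left, pr$right)), rownames(band_power))
  if (length(missing)) {
    stop("band power matrix is missing pair channels: ",
         paste(missing, collapse = ", "))
  }
  v <- asymmetry_index(band_power[pr$right, band], band_power[pr$left, band])
  names(v) <- paste0("asym:", band, ":", pr$left, "-", pr$right)
  v
}

#' Welch magnitude-squared coherence, averaged per band
#'
#' Coherence between every pair of channels, estimated from Hann-tapered
#' overlapping segments (`|S_xy|^2 / (S_xx S_yy)` with cross/auto spectra
#' averaged over segments), then averaged over the frequency bins inside each
#' band.
#'
#' @param x Channels x samples numeric matrix (with rownames), or an
#'   `eeg_recording`.
#' @param fs Sampling rate (taken from the recording if one is given).
#' @param band_edges Named list of band edges (Hz).
#' @param seg_sec Segment length in seconds (default 1).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return Named list, one symmetric channels x channels coherence matrix per
#'   band (unit diagonal).
#' @export
coherence_bands <- function(x, fs = NULL, band_edges = .default_bands(),
                            seg_sec = 1, overlap = 0.5) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    x <- x$signal
  }
  stopifnot(!is.null(fs))
  n_ch <- nrow(x)
  n <- ncol(x)
  L <- round(seg_sec * fs)
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  K <- length(starts)
  if (n < L || K < 2) {
    stop("need at least 2 averaging segments (single-segment coherence is ",
         "identically 1); got ", if (n < L) 0 else K)
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  # segment FFTs: L x (K * n_ch)
  segmat <- matrix(0, L, K * n_ch)
  for (s in seq_len(K)) {
    seg <- x[, starts[s]:(starts[s] + L - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    segmat[, ((s - 1) * n_ch + 1):(s * n_ch)] <- t(seg) * taper
  }
  F <- stats::mvfft(segmat)
  nf <- L %/% 2 + 1
  freq <- (seq_len(nf) - 1) * fs / L
  bands <- names(band_edges)
  acc <- stats::setNames(lapply(bands, function(b) matrix(0, n_ch, n_ch)), bands)
  cnt <- stats::setNames(numeric(length(bands)), bands)
  for (f in seq_len(nf)) {
    b_idx <- NULL
    for (b in bands) {
      be <- band_edges[[b]]
      # strictly inside the band edges: a bin exactly on a shared edge
      # belongs to neither band (it mixes both bands' power)
      if (freq[f] > be[1] && freq[f] < be[2]) { b_idx <- b; break }
    }
    if (is.null(b_idx)) next
    A <- matrix(F[f, ], n_ch, K)               # channels x segments at bin f
    S <- tcrossprod(A, Conj(A)) / K            # averaged cross-spectra
    p <- Re(diag(S))
    msc <- Mod(S)^2 / outer(p, p)
    acc[[b_idx]] <- acc[[b_idx]] + msc
    cnt[b_idx] <- cnt[b_idx] + 1
  }
  for (b in bands) {
    if (cnt[b] == 0) stop("no frequency bins fall inside band ", b)
    m <- acc[[b]] / cnt[b]
    m <- (m + t(m)) / 2
    m[m > 1] <- 1
    dimnames(m) <- list(rownames(x), rownames(x))
    acc[[b]] <- m
  }
  acc
}

#' Left--right interhemispheric coherence grid
#'
#' The left x right sub-block of the full coherence matrix for every band
#' (625 = 25 x 25 pairs per band with the default montage).
#'
#' @param x An `eeg_recording`/`eeg_window` or channels x samples matrix with
#'   rownames.
#' @inheritParams coherence_bands
#' @param montage An `eeg_montage`; all left/right labels must be present.
#' @return Named list per band of |left| x |right| coherence matrices.
#' @export
interhemispheric_coherence <- function(x, montage, fs = NULL,
                                       band_edges = .default_bands(),
                                       seg_sec = 1, overlap = 0.5) {
  labels <- if (inherits(x, "eeg_recording")) x$channel_labels else rownames(x)
  missing <- setdiff(c(montage$left, montage$right), labels)
  if (length(missing)) {
    stop("missing montage channels: ", paste(missing, collapse = ", "))
  }
  full <- coherence_bands(x, fs = fs, band_edges = band_edges,
                          seg_sec = seg_sec, overlap = overlap)
  lapply(full, function(m) m[montage$left, montage$right, drop = FALSE])
}
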