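## Synthetic resting-state EEG cohorts with controllable band power, 1/f
## background slope, interhemispheric coherence and ocular artifacts. Gives
## every downstream stage a ground-truthed input.

#' Default per-group band amplitude profile
#'
#' Amplitude weights (nominal microvolt SD of each band-limited oscillator).
#' The defaults encode the reported group directions at resting state: theta
#' amplitude higher in healthy controls (HC:MDD = 1.5:1) and beta amplitude
#' higher in patients (MDD:HC = 1.5:1); delta, alpha and gamma are matched.
#' Effect magnitudes are free parameters of the simulation, not estimates.
#'
#' @return Named list with `HC` and `MDD` numeric band-weight vectors.
#' @export
default_band_profile <- function() {
  list(
    HC  = c(delta = 2.0, theta = 1.8, alpha = 3.0, beta = 1.0, gamma = 0.5),
    MDD = c(delta = 2.0, theta = 1.2, alpha = 3.0, beta = 1.5, gamma = 0.5)
  )
}

#' Default interhemispheric coherence targets
#'
#' Alpha-band hypercoherence in the patient group over two central/parietal
#' homologous pairs, the direction reported for depression in the
#' quantitative-EEG coherence literature.
#'
#' @return Data frame with columns `left`, `right`, `band`, `hc`, `mdd`.
#' @export
default_coherence_targets <- function() {
  data.frame(left = c("C3", "P3"), right = c("C4", "P4"),
             band = "alpha", hc = 0.3, mdd = 0.6,
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' @param n_mdd,n_hc Group sizes (defaults 21 and 21).
#' @param n_channels Channel count; must have a built-in or supplied montage
#'   (default 58).
#' @param fs Sampling rate in Hz (default 500).
#' @param duration Recording length in seconds (default 300).
#' @param band_power_profile Per-group band amplitude weights
#'   (see [default_band_profile()]).
#' @param coherence_targets Data frame with columns `left`, `right`, `band`
#'   and either `coherence` (both groups) or `hc` and `mdd` (per-group
#'   targets), each in [0, 1]. Pairs whose channels are absent from the
#'   montage are ignored.
#' @param background_exponent Spectral slope beta of the 1/f^beta background,
#'   per group (named vector; default 1 for both).
#' @param background_amplitude Background SD in microvolts (default 1).
#' @param artifact_rate Eye-blink rate in blinks per minute (default 0: no
#'   ocular artifacts unless requested).
#' @param blink_amplitude Peak blink amplitude at the frontopolar channels in
#'   microvolts (default 80).
#' @param subject_sd Log-scale SD of the per-subject, per-band amplitude gain
#'   (default 0.08), modelling between-subject variability.
#' @param montage Optional `eeg_montage`; defaults to
#'   `generate_montage(n_channels)`.
#' @param seed Integer seed; the spec plus seed fully determines the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mdd = 21, n_hc = 21, n_channels = 58, fs = 500,
                        duration = 300,
                        band_power_profile = default_band_profile(),
                        coherence_targets = default_coherence_targets(),
                        background_exponent = c(HC = 1, MDD = 1),
                        background_amplitude = 1,
                        artifact_rate = 0,
                        blink_amplitude = 80,
                        subject_sd = 0.08,
                        montage = NULL,
                        seed = 1L) {
  stopifnot(n_mdd >= 0, n_hc >= 0, fs > 0, duration > 0,
            background_amplitude >= 0, artifact_rate >= 0)
  if (is.null(montage)) montage <- generate_montage(n_channels)
  for (g in c("HC", "MDD")) {
    if (any(band_power_profile[[g]] < 0)) stop("band weights must be non-negative")
  }
  ct <- coherence_targets
  if (!is.null(ct) && nrow(ct)) {
    if (!all(c("hc", "mdd") %in% names(ct))) {
      ct$hc <- ct$mdd <- ct$coherence
    }
    if (any(ct$hc < 0 | ct$hc > 1 | ct$mdd < 0 | ct$mdd > 1)) {
      stop("coherence targets must lie in [0, 1]")
    }
    present <- ct$left %in% montage_labels(montage) &
      ct$right %in% montage_labels(montage)
    ct <- ct[present, , drop = FALSE]
  }
  structure(
    list(n_mdd = as.integer(n_mdd), n_hc = as.integer(n_hc),
         n_channels = as.integer(n_channels), fs = fs, duration = duration,
         band_power_profile = band_power_profile,
         coherence_targets = ct,
         background_exponent = background_exponent,
         background_amplitude = background_amplitude,
         artifact_rate = artifact_rate,
         blink_amplitude = blink_amplitude,
         subject_sd = subject_sd,
         montage = montage, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# 1/f^beta noise by spectral synthesis, unit SD
.pink_noise <- function(n, beta, fs) {
  w <- stats::rnorm(n)
  if (beta == 0) return(w)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                    # avoid DC blow-up
  f <- pmin(f, n - f + 1) * fs / n             # two-sided frequency axis
  W <- W * f^(-beta / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

# band-limited oscillator: band-pass-filtered white noise, unit SD; the
# filter is applied twice so band skirts are steep enough that neighbouring
# oscillators dilute in-band coherence only marginally
.narrowband <- function(n, fs, band) {
  x <- stats::rnorm(n)
  flt <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(flt, signal::filtfilt(flt, x))
  y / stats::sd(y)
}

# stereotyped 400-ms biphasic blink template
.blink_template <- function(fs) {
  t <- seq(0, 0.4, by = 1 / fs)
  sin(2 * pi * t / 0.4) * (0.5 - 0.5 * cos(2 * pi * t / 0.4))
}

# exponentially decaying frontal topography by label prefix
.frontal_topography <- function(labels) {
  w <- rep(0.02, length(labels))
  w[grepl("^(FC|FT)", labels, ignore.case = TRUE)] <- 0.15
  w[grepl("^(F|AF)[0-9z]", labels, ignore.case = TRUE) &
      !grepl("^(FC|FT)", labels, ignore.case = TRUE)] <- 0.4
  w[grepl("^(AF)", labels, ignore.case = TRUE)] <- 0.6
  w[grepl("^Fp", labels, ignore.case = TRUE)] <- 1
  w
}

# cache of calibrated shared-source mixing weights
.coh_cache <- new.env(parent = emptyenv())

# solve the shared-source mixing fraction lambda against the package's own
# coherence estimator by bisection on a fixed-seed probe pair; the probe
# carries the full per-channel model (all band oscillators + background) so
# that spectral leakage from neighbouring bands is accounted for
.calibrate_mixing <- function(target, band_name, profile, bg_amp, beta, fs,
                              probe_sec = 30) {
  key <- paste(round(target, 4), band_name,
               paste(round(profile, 4), collapse = ","),
               round(bg_amp, 4), beta, fs, sep = "|")
  hit <- get0(key, envir = .coh_cache)
  if (!is.null(hit)) return(hit)
  n <- round(probe_sec * fs)
  band_edges <- .default_bands()[names(profile)]
  withr_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(20201L)
  s <- .narrowband(n, fs, band_edges[[band_name]])
  n1 <- .narrowband(n, fs, band_edges[[band_name]])
  n2 <- .narrowband(n, fs, band_edges[[band_name]])
  other1 <- numeric(n); other2 <- numeric(n)
  for (b in setdiff(names(profile), band_name)) {
    if (profile[[b]] == 0) next
    other1 <- other1 + profile[[b]] * .narrowband(n, fs, band_edges[[b]])
    other2 <- other2 + profile[[b]] * .narrowband(n, fs, band_edges[[b]])
  }
  b1 <- .pink_noise(n, beta, fs)
  b2 <- .pink_noise(n, beta, fs)
  if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv())
  w_b <- profile[[band_name]]
  bands <- band_edges[band_name]
  est <- function(lam) {
    x1 <- w_b * (sqrt(lam) * s + sqrt(1 - lam) * n1) + other1 + bg_amp * b1
    x2 <- w_b * (sqrt(lam) * s + sqrt(1 - lam) * n2) + other2 + bg_amp * b2
    m <- rbind(x1, x2)
    rownames(m) <- c("a", "b")
    coherence_bands(m, fs = fs, band_edges = bands)[[band_name]][1, 2]
  }
  if (target <= 0 || w_b == 0) {
    lam <- 0
  } else if (est(1) <= target) {
    lam <- 1
  } else {
    lo <- 0; hi <- 1
    for (i in 1:12) {
      mid <- (lo + hi) / 2
      if (est(mid) < target) lo <- mid else hi <- mid
    }
    lam <- (lo + hi) / 2
  }
  assign(key, lam, envir = .coh_cache)
  lam
}

#' Generate one synthetic subject
#'
#' The signal is a sum of band-limited oscillators (band-pass-filtered white
#' noise, one per band and channel, scaled by the group's band amplitude
#' profile and a per-subject gain), a 1/f^beta background, and optional
#' stereotyped blink artifacts at Poisson times mixed through a frontal
#' topography. Channel pairs named in the spec's coherence targets share a
#' common band-limited source whose mixing weight is calibrated numerically
#' against [coherence_bands()].
#'
#' @param spec A [cohort_spec()].
#' @param group `"MDD"` or `"HC"`.
#' @param seed Integer seed for this subject.
#' @param subject_id Subject identifier.
#' @return An `eeg_recording`. When blinks are simulated, the ground-truth
#'   blink time course and channel topography are attached as attributes
#'   `"blink_source"` and `"blink_topography"`.
#' @export
generate_subject <- function(spec, group = c("HC", "MDD"), seed = spec$seed,
                             subject_id = "s01") {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  mont <- spec$montage
  labels <- montage_labels(mont)
  n_ch <- length(labels)
  n <- round(spec$duration * spec$fs)
  beta <- unname(spec$background_exponent[group])
  profile <- spec$band_power_profile[[group]]
  band_edges <- .default_bands()[names(profile)]

  ct <- spec$coherence_targets
  # calibrate mixing weights before touching the subject RNG stream
  lam_tab <- NULL
  if (!is.null(ct) && nrow(ct)) {
    tcol <- if (group == "MDD") ct$mdd else ct$hc
    lam_tab <- vapply(seq_len(nrow(ct)), function(i) {
      .calibrate_mixing(tcol[i], ct$band[i], profile,
                        spec$background_amplitude, beta, spec$fs)
    }, 0)
  }

  set.seed(seed)
  sig <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    sig[ch, ] <- spec$background_amplitude * .pink_noise(n, beta, spec$fs)
  }
  gains <- exp(stats::rnorm(length(profile), 0, spec$subject_sd))
  names(gains) <- names(profile)
  for (b in names(profile)) {
    w_b <- profile[[b]] * gains[[b]]
    if (w_b == 0) next
    paired <- character(0)
    if (!is.null(ct) && nrow(ct)) {
      in_band <- which(ct$band == b)
      for (i in in_band) {
        lam <- lam_tab[i]
        s <- .narrowband(n, spec$fs, band_edges[[b]])
        n1 <- .narrowband(n, spec$fs, band_edges[[b]])
        n2 <- .narrowband(n, spec$fs, band_edges[[b]])
        il <- match(ct$left[i], labels)
        ir <- match(ct$right[i], labels)
        sig[il, ] <- sig[il, ] + w_b * (sqrt(lam) * s + sqrt(1 - lam) * n1)
        sig[ir, ] <- sig[ir, ] + w_b * (sqrt(lam) * s + sqrt(1 - lam) * n2)
        paired <- c(paired, ct$left[i], ct$right[i])
      }
    }
    for (ch in which(!labels %in% paired)) {
      sig[ch, ] <- sig[ch, ] + w_b * .narrowband(n, spec$fs, band_edges[[b]])
    }
  }

  blink_source <- NULL
  topo <- NULL
  if (spec$artifact_rate > 0) {
    n_blinks <- stats::rpois(1, spec$artifact_rate * spec$duration / 60)
    tmpl <- .blink_template(spec$fs)
    blink_source <- numeric(n)
    if (n_blinks > 0) {
      onsets <- sort(stats::runif(n_blinks, 0, spec$duration - 0.4))
      for (t0 in onsets) {
        i0 <- round(t0 * spec$fs) + 1
        idx <- i0:(i0 + length(tmpl) - 1)
        keep <- idx <= n
        blink_source[idx[keep]] <- blink_source[idx[keep]] + tmpl[keep]
      }
    }
    topo <- .frontal_topography(labels)
    sig <- sig + spec$blink_amplitude * outer(topo, blink_source)
  }

  rec <- recording(sig, fs = spec$fs, channel_labels = labels,
                   group = group, subject_id = subject_id)
  if (!is.null(blink_source)) {
    attr(rec, "blink_source") <- blink_source
    attr(rec, "blink_topography") <- topo
  }
  rec
}

#' Generate a full synthetic cohort
#'
#' `n_mdd + n_hc` recordings, deterministic given the spec (including its
#' seed): the same spec always yields bit-identical signals.
#'
#' @param spec A [cohort_spec()].
#' @return List of `eeg_recording` objects (MDD subjects first).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- vector("list", spec$n_mdd + spec$n_hc)
  k <- 0
  for (i in seq_len(spec$n_mdd)) {
    k <- k + 1
    recs[[k]] <- generate_subject(spec, "MDD", seed = spec$seed + 1009L * k,
                                  subject_id = sprintf("mdd%02d", i))
  }
  for (i in seq_len(spec$n_hc)) {
    k <- k + 1
    recs[[k]] <- generate_subject(spec, "HC", seed = spec$seed + 1009L * k,
                                  subject_id = sprintf("hc%02d", i))
  }
  recs
}
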