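test_that("detrending removes offsets and linear drifts and is idempotent", {
  fs <- 100
  t <- seq_len(1000)
  trend <- recording(matrix(2 + 0.01 * t, 1), fs, "C3")
  out <- detrend_recording(trend)
  expect_lt(max(abs(out$signal)), 1e-9)

  # integer periods, symmetric about the window centre: the oscillation is
  # orthogonal to the line basis and survives detrending unchanged
  x <- cos(2 * pi * 10 * (t - mean(t)) / fs)
  rec <- recording(matrix(x + 5, 1), fs, "C3")
  out <- detrend_recording(rec)
  expect_lt(mean(abs(out$signal[1, ] - x)), 1e-9)

  once <- detrend_recording(rec)
  twice <- detrend_recording(once)
  expect_equal(twice$signal, once$signal, tolerance = 1e-12)
})

test_that("band-pass keeps the passband, rejects stopband and DC", {
  fs <- 500
  n <- 10 * fs
  t <- seq_len(n) / fs
  mk <- function(x) recording(matrix(x, 1), fs, "C3")
  amp <- function(rec) sqrt(mean(rec$signal[1, fs:(9 * fs)]^2)) * sqrt(2)

  expect_gt(amp(bandpass_recording(mk(sin(2 * pi * 10 * t)))), 0.95)
  expect_lt(amp(bandpass_recording(mk(sin(2 * pi * 10 * t)))), 1.05)
  atten_db <- 20 * log10(amp(bandpass_recording(mk(sin(2 * pi * 100 * t)))))
  expect_lt(atten_db, -20)
  dc <- bandpass_recording(mk(rep(5, n)))
  expect_lt(mean(abs(dc$signal)), 0.05)

  expect_error(bandpass_recording(mk(t), low = 50, high = 0.5), "low")
  expect_error(bandpass_recording(mk(t), low = 0.5, high = 400), "fs/2")
})

test_that("ICA with no rejection reconstructs the input", {
  rec <- noise_recording(5, seconds = 4, seed = 11)
  out <- ica_clean(rec, n_components = 5)
  rel <- norm(out$signal - rec$signal, "F") / norm(rec$signal, "F")
  expect_lt(rel, 1e-6)
  expect_length(attr(out, "rejected_components"), 0)
})

test_that("ICA recovers randomly mixed sources up to permutation and sign", {
  set.seed(21)
  n <- 4000
  S0 <- rbind(sin(2 * pi * 5 * seq_len(n) / 500),
              runif(n) - 0.5,
              rnorm(n)^3)
  A0 <- qr.Q(qr(matrix(rnorm(9), 3)))
  dec <- fastica(A0 %*% S0, 3, seed = 2)
  cors <- abs(stats::cor(t(dec$S), t(S0)))
  expect_true(all(apply(cors, 2, max) > 0.95))
})

test_that("rejecting components zeroes them; bad indices error", {
  rec <- noise_recording(4, seconds = 3, seed = 5)
  out <- ica_clean(rec, n_components = 4, reject = 1:4)
  expect_lt(max(abs(out$signal - rowMeans(rec$signal))), 1e-9)
  expect_error(ica_clean(rec, n_components = 4, reject = 9), "out of range")
})

test_that("template-based ICA cleanup removes a known blink artifact", {
  spec <- cohort_spec(n_mdd = 1, n_hc = 0, n_channels = 6, fs = 500,
                      duration = 20, artifact_rate = 20, seed = 31)
  rec <- generate_subject(spec, "MDD", seed = 31)
  blink <- attr(rec, "blink_source")
  frontal <- which.max(attr(rec, "blink_topography"))
  pre <- abs(stats::cor(rec$signal[frontal, ], blink))
  expect_gt(pre, 0.5)
  clean <- ica_clean(rec, n_components = 6, templates = blink, seed = 1)
  post <- abs(stats::cor(clean$signal[frontal, ], blink))
  expect_lt(post, 0.1)
  expect_gte(length(attr(clean, "rejected_components")), 1)
})

test_that("segmentation floors to whole windows and warns when too short", {
  rec <- noise_recording(2, seconds = 30, fs = 500, seed = 7)
  wins <- segment_recording(rec, 2)
  expect_length(wins, 15)
  expect_true(all(vapply(wins, function(w) ncol(w$signal), 0) == 1000))
  expect_equal(vapply(wins, function(w) w$window_index, 0L), 1:15)

  rec2 <- noise_recording(1, seconds = 5.5, fs = 100)
  expect_length(segment_recording(rec2, 2), 2)

  rec3 <- noise_recording(1, seconds = 1.9, fs = 100)
  expect_warning(wins3 <- segment_recording(rec3, 2), "shorter")
  expect_length(wins3, 0)
})
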