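test_that("cohort generation is deterministic and correctly sized", {
  spec <- cohort_spec(n_mdd = 2, n_hc = 3, n_channels = 4, fs = 250,
                      duration = 4, seed = 5)
  recs <- generate_cohort(spec)
  expect_length(recs, 5)
  expect_equal(vapply(recs, function(r) r$group, ""),
               c("MDD", "MDD", "HC", "HC", "HC"))
  expect_true(all(vapply(recs, function(r) ncol(r$signal), 0) == 4 * 250))

  recs2 <- generate_cohort(spec)
  for (i in seq_along(recs)) {
    expect_identical(recs[[i]]$signal, recs2[[i]]$signal)
  }
})

test_that("a subject's duration and montage define the signal shape", {
  spec <- cohort_spec(n_mdd = 1, n_hc = 0, n_channels = 6, fs = 500,
                      duration = 3, seed = 2)
  rec <- generate_subject(spec, "HC", seed = 2)
  expect_equal(dim(rec$signal), c(6, 1500))
  expect_equal(rec$channel_labels, montage_labels(spec$montage))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_mdd = -1), "n_mdd")
  expect_error(cohort_spec(
    coherence_targets = data.frame(left = "C3", right = "C4",
                                   band = "alpha", coherence = 1.4)),
    "\\[0, 1\\]")
  bad_profile <- default_band_profile()
  bad_profile$HC["theta"] <- -1
  expect_error(cohort_spec(band_power_profile = bad_profile), "non-negative")
})

test_that("a unit coherence target yields near-unit estimated coherence", {
  spec <- cohort_spec(
    n_mdd = 1, n_hc = 0, n_channels = 6, fs = 500, duration = 30,
    coherence_targets = data.frame(left = "C3", right = "C4",
                                   band = "alpha", coherence = 1.0),
    seed = 17)
  rec <- generate_subject(spec, "HC", seed = 17)
  expect_gt(coherence_bands(rec)$alpha["C3", "C4"], 0.9)
  # an uncontrolled pair stays weakly coherent
  expect_lt(coherence_bands(rec)$alpha["F3", "F4"], 0.4)
})

test_that("an intermediate coherence target is approximated", {
  spec <- cohort_spec(
    n_mdd = 1, n_hc = 0, n_channels = 6, fs = 500, duration = 60,
    coherence_targets = data.frame(left = "C3", right = "C4",
                                   band = "alpha", coherence = 0.6),
    seed = 23)
  est <- coherence_bands(generate_subject(spec, "HC", seed = 23))$alpha["C3", "C4"]
  expect_gt(est, 0.45)
  expect_lt(est, 0.75)
})

test_that("the theta effect direction is recovered by a group comparison", {
  spec <- cohort_spec(n_mdd = 8, n_hc = 8, n_channels = 4, fs = 500,
                      duration = 8, coherence_targets = NULL, seed = 77)
  recs <- generate_cohort(spec)
  theta_of <- function(rec) {
    wins <- segment_recording(bandpass_recording(detrend_recording(rec)), 2)
    mean(vapply(wins, function(w) {
      mean(relative_power(wavelet_band_decompose(w))[, "theta"])
    }, 0))
  }
  theta <- vapply(recs, theta_of, 0)
  grp <- vapply(recs, function(r) r$group, "")
  tt <- t.test(theta[grp == "HC"], theta[grp == "MDD"], var.equal = TRUE)
  expect_gt(mean(theta[grp == "HC"]), mean(theta[grp == "MDD"]))
  expect_lt(tt$p.value, 0.05)
})

test_that("a white background with no oscillators gives DFA alpha near 0.5", {
  profile <- list(HC = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
                  MDD = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0))
  spec <- cohort_spec(n_mdd = 0, n_hc = 1, n_channels = 2, fs = 500,
                      duration = 12, band_power_profile = profile,
                      coherence_targets = NULL,
                      background_exponent = c(HC = 0, MDD = 0), seed = 9)
  rec <- generate_subject(spec, "HC", seed = 9)
  a <- dfa(rec$signal[1, ])
  expect_lt(abs(a - 0.5), 0.05)
})

test_that("blink artifacts land on frontal channels with known ground truth", {
  spec <- cohort_spec(n_mdd = 1, n_hc = 0, n_channels = 6, fs = 500,
                      duration = 20, artifact_rate = 15, seed = 13)
  rec <- generate_subject(spec, "MDD", seed = 13)
  blink <- attr(rec, "blink_source")
  topo <- attr(rec, "blink_topography")
  expect_length(blink, ncol(rec$signal))
  expect_gt(sum(blink != 0), 0)
  # frontal channel correlates with the blink source, occipital hardly
  expect_gt(abs(cor(rec$signal[which.max(topo), ], blink)), 0.5)
  expect_lt(abs(cor(rec$signal[which.min(topo), ], blink)), 0.2)
})
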