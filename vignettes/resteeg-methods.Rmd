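---
title: "Resting-state EEG features and SVM classification for depression research: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state EEG differs measurably between patients with major depressive
disorder (MDD) and healthy controls (HC): group studies report lower relative
theta power and higher beta power in patients, along with altered
interhemispheric coherence. **resteeg** implements a complete, testable
version of the analysis chain used in this literature: seven per-channel or
per-pair feature families are extracted from cleaned 2-s windows, filtered by
one of two univariate selection routes, and classified with an RBF-kernel SVM
whose hyperparameters are tuned by grid search under stratified ten-fold
cross-validation. A label-permutation test and repeated random splits
quantify the evidence that the classifier exploits real group structure
rather than noise.

Because clinical EEG corpora cannot be redistributed, the package ships a
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes, so that every stage of the pipeline — including the
end-to-end classification experiment — can be validated against known ground
truth on any machine.

## Pipeline overview

1. **Preprocessing** (`detrend_recording`, `bandpass_recording`,
   `ica_clean`, `segment_recording`): per-channel least-squares detrending;
   zero-phase 0.5–50 Hz Butterworth band-pass (order-4 high-pass and
   low-pass in cascade, each run forward–backward with odd-reflection end
   padding and steady-state initialization); FastICA artifact removal; and
   segmentation into non-overlapping 2-s windows, discarding a trailing
   partial window so all windows are identical in length.
2. **Spectral features** (`wavelet_band_decompose`, `relative_power`,
   `alpha_asymmetry`, `interhemispheric_coherence`): periodized orthonormal
   Daubechies wavelet energies mapped to the five clinical bands
   (delta 0.5–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–50 Hz),
   per-channel relative power, the alpha asymmetry index
   \((R - L)/(R + L)\) over the montage's 26-pair inventory, and Welch
   magnitude-squared coherence over the 25 × 25 left–right channel grid.
3. **Network features** (`binarize`, `graph_metrics`): the full
   channel-by-channel coherence matrix per band is thresholded at 0.6 into a
   binary graph; mean degree ("strength"), mean local clustering
   coefficient, and characteristic path length are reported per band.
4. **Complexity features** (`sampen`, `mse`, `dfa`): band-filtered sample
   entropy (m = 2, r = 0.2 SD, Chebyshev distance, self-matches excluded),
   multiscale entropy summed over coarse-graining scales 1–10, and the
   detrended-fluctuation scaling exponent over a log-spaced window grid.
5. **Selection and classification** (`ttest_select`, `auc_rank_select`,
   `sweep_k`, `grid_search`, `repeat_experiment`, `permutation_test`):
   subject-stratified 80/20 splits, z-scoring with training statistics only,
   pooled-variance t-tests at α = 0.05 or |AUC − 0.5| ranking with an
   incremental feature-count sweep, and an RBF SVM tuned over a
   log₁₀ grid of cost and kernel width (the full grid spans 10⁻¹⁰…10¹⁰ in
   10^0.2 steps; 101 × 101 candidates).

## The synthetic cohort generator

`generate_cohort()` draws each subject as a sum of three parts:

* **Band-limited oscillators** — white noise band-pass filtered into each of
  the five bands (the filter applied twice, so skirts are steep), scaled by
  the group's band amplitude profile in nominal µV. Filtered noise rather
  than pure sinusoids is essential: sinusoids have degenerate sample entropy
  and razor-thin spectra, and would make the complexity features
  meaningless. The default profile encodes only the *directions* reported
  for resting EEG in depression — theta amplitude 1.5× higher in HC, beta
  amplitude 1.5× higher in MDD, other bands matched. Magnitudes are free
  simulation parameters, since group effect sizes are not published
  numerically.
* **1/f^β background** — spectrally synthesized noise with slope β
  (default 1) per group and SD 1 µV. With β = 0 and all oscillators off the
  generator emits white noise, which is how the DFA operator's α ≈ 0.5 limit
  is checked.
* **Ocular artifacts** (optional) — a stereotyped 400-ms biphasic blink
  template placed at Poisson times, mixed through a frontally weighted
  topography. The true blink time course and topography are attached to the
  recording, giving ICA-removal tests an objective target.

Homologous channel pairs listed in the spec's coherence targets share a
common band-limited source. The mixing weight is solved numerically by
bisection against the package's own coherence estimator on a fixed-seed
probe pair that carries the full per-channel model (all bands plus
background), because neighbouring bands leak a little power into the target
band and an analytic weight would overshoot. Identical spec (including the
seed) always reproduces bit-identical signals.

What the generator does **not** emulate: volume conduction and a head-model
forward projection, non-stationary state changes (drowsiness), electrode
artifacts other than blinks, and any realistic covariance between feature
families. Passing tests on synthetic cohorts therefore demonstrates that the
pipeline recovers the statistical structure it assumes — not that the
published clinical accuracies transfer to any particular real dataset.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `window_length` | 2 | s | analysis window; 150 windows from a 5-min record |
| band edges | 0.5–4–8–12–30–50 | Hz | alpha is 8–12 (the Methods convention; 8–13 appears in some figure captions and can be configured) |
| `coherence_threshold` | 0.6 | – | network binarization |
| `sampen_m`, `sampen_r` | 2, 0.2 | –, × SD | universal EEG SampEn convention; not published in the source analyses |
| `mse_scales` | 10 | – | ⌊1000/10⌋ = 100 samples at the coarsest scale, above the m + 1 floor |
| `dfa_window_lengths` | 4…211 | samples | log-spaced, clipped to ≤ N/4 |
| `selection_alpha` | 0.05 | – | t-test route |
| `train_fraction` | 0.8 | – | subject-stratified split |
| SVM grid | 10⁻¹⁰…10¹⁰, step 10^0.2 | – | 101 × 101 candidates |
| `n_repeats`, `n_permutations` | 100, 100 | – | published repetition counts |

## Numerical choices and conventions

* **Wavelet family.** Band powers use the periodized orthonormal **db8**
  pyramid with 7 levels at 500 Hz, mapping detail levels to bands by maximal
  log-frequency overlap (gamma ≈ D3, beta ≈ D4, alpha ≈ D5, theta ≈ D6,
  delta ≈ D7 + A7). We evaluated db4 first: its slow spectral roll-off
  leaves only ~0.76–0.80 of a 10 Hz sinusoid's energy in the alpha level,
  badly blurring adjacent bands, while db8 concentrates ~0.90 there at
  negligible extra cost. Orthonormality gives exact Parseval energy
  accounting (tested).
* **Coherence estimator.** Welch cross-spectra with 1-s Hann-tapered
  segments at 50% overlap, estimated per cleaned recording rather than per
  2-s window: a 2-s window yields at most 3 averaging segments, which makes
  single-window coherence estimates nearly degenerate (a lone segment is
  identically 1). Per-window estimation remains available via
  `coherence_unit = "window"`. Band values average the frequency bins
  strictly *inside* the band edges; a bin sitting exactly on a shared edge
  mixes both bands' power and belongs to neither.
* **Sample entropy.** Both ψ_m and ψ_{m+1} count pairs over the same
  template index range (the Richman–Moorman convention) with strict
  inequality against the tolerance, so the conditional probability is well
  defined; counts are computed in C++ with a first-coordinate sort prune
  that leaves the counts bit-identical to the literal double loop (tested
  against that oracle on every run of the suite).
* **Multiscale entropy.** The tolerance r is fixed at 0.2 × the SD of the
  original series for *all* scales. Re-estimating r per scale cancels the
  variance reduction that coarse-graining produces and flattens the
  white-noise scale curve (we measured ~50% monotone-decreasing seeds
  versus ~100% with fixed r); fixed r is also the original multiscale
  convention. The per-scale curve is attached to every `mse()` result.
* **DFA.** Linear (order-1) detrending per window, fluctuation pooled as the
  RMS over all profile points, α by least squares of log F(n) on log n;
  window lengths below 4 samples or above N/4 are excluded and fewer than 3
  usable lengths is an error.
* **Graph metrics.** Strength on a binary graph equals degree. Nodes of
  degree < 2 contribute clustering 0. For disconnected graphs L averages
  over reachable pairs only, with the unreachable fraction reported — the
  alternative (assigning n) distorts sparse graphs far more. An edgeless
  graph reports L = NA.
* **Grid-search tie-break.** Exact CV-accuracy ties go to the smallest cost,
  then the smallest gamma, preferring smoother models and making the search
  deterministic.
* **Empty selections.** If no feature survives the filter (possible on
  permuted labels), the single best-ranked feature is used so that the
  permutation replicate still yields an accuracy instead of aborting the
  null distribution.
* **Plateau rule for the feature-count sweep.** The published procedure
  picks the "turning point" of the accuracy curve visually; `sweep_k`
  formalizes it as the smallest k reaching ≥ 95% of the curve's maximum
  with no gain of more than one accuracy point over the next three grid
  points.

## Design choices where the design was open

* **The 26-pair inventory.** Removing the 8 midline channels from 58 leaves
  25 homologous pairs, yet 26 asymmetry indices and a 25-per-side coherence
  grid are both published counts. No single partition yields both, so the
  montage stores the pair inventory as explicit data: the 25 homologous
  pairs plus one additional anterior cross-pair (AF3–Fp2) as the 26th entry.
  Users analyzing real data should replace it with their lab's inventory via
  a montage JSON.
* **Sample unit and leakage.** Windows are the default sample unit (matching
  the published test-set granularity), but splits are *subject*-stratified:
  every window of a subject lands on one side of the split. A purely
  row-level random split (`split_unit = "window"`) is available for
  comparison, but it leaks subject identity across the split and inflates
  test accuracy.
* **Reporting vs modeling statistics.** Descriptive group comparisons may
  use all subjects, but the selection statistics inside the modeling path
  are always computed on training rows only; the interface makes the leak
  impossible rather than discouraged (test rows are never passed in).
* **ICA rejection.** Manual visual component rejection is not automatable
  faithfully, so the interface takes either an explicit component index list
  (real data) or reference artifact time courses with an absolute-correlation
  threshold of 0.5 (synthetic data, where the blink ground truth is known).
  The published exclusion rule for subjects with many noisy components is
  surfaced as the number of rejected components per recording, not as an
  automatic exclusion.
* **Permutation scope.** The permutation test re-runs feature selection
  inside every permutation by default — the statistically valid reading of
  re-running "these processes" — with a cheaper fixed-feature variant
  (`refit_selection = FALSE`) available.

## Problem sizes used by the test-suite and acceptance script

The published study conditions (58 channels, 500 Hz, 5 min, 21 + 21
subjects, 100 repeats, 100 permutations, 101 × 101 grid) are the package
defaults. The automated checks exercise the same code paths at smaller,
fixed sizes chosen once: toy montages of 4–6 channels, 10–12 s records
(5–6 windows per subject), 20 repeats, 24 permutations, and a coarser
5 × 5 hyperparameter grid for the end-to-end experiment, with the full
58-channel montage used for the structural-count and coherence-grid checks.
At these sizes the injected theta/beta/coherence effects are large and the
end-to-end mean test accuracy on the synthetic cohort exceeds 85% with a
permutation p below 0.05, while no-effect cohorts stay at chance.

## Known limitations

* The EDF writer/reader covers the continuous 16-bit EDF layout with a
  uniform sampling rate; EDF+ annotations and discontinuous records are out
  of scope.
* Coherence is magnitude-squared coherence only; phase-based connectivity
  (PLV, imaginary coherence) is deliberately excluded.
* The t-test route applies no multiple-testing correction — faithful to the
  published procedure, and one reason its selected-feature counts are large.
* Published accuracies on the original clinical dataset are not a target of
  the automated checks: they depend on data that must be downloaded and
  converted by the user (`read_recording` accepts EDF or matrix + sidecar
  once converted).
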