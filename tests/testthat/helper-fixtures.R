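# Small in-code fixtures shared across test files.

toy_montage <- function(n = 6) generate_montage(n)

sine_window <- function(freq, fs = 500, seconds = 2, label = "C3") {
  t <- seq_len(round(fs * seconds)) / fs
  as_window(recording(matrix(sin(2 * pi * freq * t), 1), fs, label), 1L)
}

noise_recording <- function(n_ch = 2, seconds = 10, fs = 500, seed = 1,
                            labels = paste0("ch", seq_len(n_ch))) {
  set.seed(seed)
  recording(matrix(rnorm(n_ch * round(seconds * fs)), n_ch), fs, labels)
}

# gaussian feature table: `shift` moves the MDD class mean on every feature
gaussian_table <- function(n_per_class = 20, n_features = 30, shift = 0,
                           seed = 1) {
  set.seed(seed)
  mk <- function(grp, n, delta) {
    X <- matrix(rnorm(n * n_features, mean = delta), n)
    colnames(X) <- sprintf("f%03d", seq_len(n_features))
    data.frame(subject_id = sprintf("%s%02d", tolower(grp), seq_len(n)),
               window_index = 1L, group = grp, X, check.names = FALSE)
  }
  feature_table(rbind(mk("MDD", n_per_class, shift), mk("HC", n_per_class, 0)))
}

# tiny synthetic EEG cohort, cached per-session to keep the suite fast
.fixture_env <- new.env(parent = emptyenv())

small_cohort_spec <- function(...) {
  cohort_spec(n_mdd = 4, n_hc = 4, n_channels = 6, fs = 500, duration = 10,
              seed = 421L, ...)
}

small_cohort_table <- function() {
  hit <- get0("small_tab", envir = .fixture_env)
  if (!is.null(hit)) return(hit)
  spec <- small_cohort_spec()
  cfg <- run_config(seed = 421L)
  tab <- extract_features(generate_cohort(spec), spec$montage, cfg)
  assign("small_tab", tab, envir = .fixture_env)
  tab
}

# the full-size synthetic study cohort: 21 + 21 subjects with the default
# injected theta/beta/coherence effects, extracted once per session
effect_cohort_table <- function() {
  hit <- get0("effect_tab", envir = .fixture_env)
  if (!is.null(hit)) return(hit)
  spec <- cohort_spec(n_mdd = 21, n_hc = 21, n_channels = 6, fs = 500,
                      duration = 12, seed = 1001L)
  tab <- extract_features(generate_cohort(spec), spec$montage,
                          run_config(seed = 1001L))
  assign("effect_tab", tab, envir = .fixture_env)
  tab
}

effect_cohort_config <- function() {
  run_config(svm_grid = svm_grid(c(-5, 5), c(-5, 5), 2.5),
             n_repeats = 20, n_permutations = 24,
             split_unit = "subject", seed = 1001L)
}
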