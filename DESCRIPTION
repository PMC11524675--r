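Package: resteeg
Title: Resting-State EEG Features and Classification for Depression Research
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for discriminating patients with major
    depressive disorder from healthy controls using resting-state EEG.
    Implements seven feature families (relative band power, alpha
    interhemispheric asymmetry, left-right magnitude-squared coherence,
    binarized network metrics, sample entropy, multiscale entropy and
    detrended fluctuation analysis), two filter-based feature-selection
    routes (pooled-variance t-test and AUC ranking), and RBF-kernel SVM
    classification with grid search, stratified ten-fold cross-validation,
    repeated evaluation and label-permutation testing. A synthetic-EEG
    cohort generator with controllable band power, spectral slope,
    interhemispheric coherence and ocular artifacts provides
    ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
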