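## RBF-SVM classification: log-grid hyperparameter search with stratified
## ten-fold CV, test-set evaluation, repeated experiments and the
## label-permutation validity test.

#' Hyperparameter grid for the RBF SVM
#'
#' Log10 ranges for cost and kernel width. The full published grid
#' (`10^-10 .. 10^10` in `10^0.2` steps, 101 x 101 candidates) is the
#' default; coarser grids are used for desk-scale runs.
#'
#' @param c_range,g_range `c(min, max)` log10 exponent ranges.
#' @param step Exponent step (default 0.2).
#' @return An object of class `svm_grid`.
#' @export
svm_grid <- function(c_range = c(-10, 10), g_range = c(-10, 10), step = 0.2) {
  stopifnot(c_range[1] < c_range[2], g_range[1] < g_range[2], step > 0)
  structure(list(c_range = c_range, g_range = g_range, step = step),
            class = "svm_grid")
}

#' Candidate (cost, gamma) pairs of a grid
#' @param grid An `svm_grid`.
#' @return Data frame with columns `c_exp` and `g_exp` (log10 exponents),
#'   ordered by cost then gamma (the tie-break order).
#' @export
grid_candidates <- function(grid) {
  cs <- seq(grid$c_range[1], grid$c_range[2], by = grid$step)
  gs <- seq(grid$g_range[1], grid$g_range[2], by = grid$step)
  data.frame(c_exp = rep(cs, each = length(gs)), g_exp = rep(gs, length(cs)))
}

# deterministic stratified fold assignment
.stratified_folds <- function(y, folds, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  id <- integer(length(y))
  for (g in unique(y)) {
    idx <- sample(which(y == g))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Grid search with stratified k-fold cross-validation
#'
#' Evaluates every (cost, gamma) candidate by mean stratified CV accuracy and
#' returns the best pair; exact accuracy ties are broken toward the smallest
#' cost, then the smallest gamma (preferring smoother models).
#'
#' @param x Numeric feature matrix (training rows).
#' @param y Group labels (`"MDD"`/`"HC"`).
#' @param grid An [svm_grid()].
#' @param folds CV folds (default 10); reduced with a warning when the
#'   smaller class has fewer members.
#' @param seed Seed for the fold shuffler.
#' @return List with `cost`, `gamma`, their log10 exponents, and
#'   `cv_accuracy` (fraction).
#' @export
grid_search <- function(x, y, grid = svm_grid(), folds = 10, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("HC", "MDD"))
  if (any(is.na(y))) stop("labels must be MDD or HC")
  min_class <- min(table(y))
  if (min_class < 2) stop("need at least 2 samples per class")
  if (min_class < folds) {
    warning("reducing folds from ", folds, " to ", min_class,
            " (smallest class size)")
    folds <- min_class
  }
  fold_id <- .stratified_folds(y, folds, seed)
  cand <- grid_candidates(grid)
  acc <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    correct <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                        type = "C-classification", kernel = "radial",
                        cost = 10^cand$c_exp[i], gamma = 10^cand$g_exp[i],
                        scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc[i] <- correct / length(y)
  }
  best <- which.max(acc)   # first max = smallest c, then smallest g
  list(cost = 10^cand$c_exp[best], gamma = 10^cand$g_exp[best],
       c_exp = cand$c_exp[best], g_exp = cand$g_exp[best],
       cv_accuracy = acc[best])
}

#' Evaluate a fitted classifier on test rows
#'
#' MDD is the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). Rates are reported in percent; a rate whose
#' class is absent from the test set is `NA`.
#'
#' @param model A fitted `e1071::svm` model (or anything `predict`-able to
#'   HC/MDD labels).
#' @param x Test feature matrix.
#' @param y True labels.
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   the confusion counts.
#' @export
evaluate_model <- function(model, x, y) {
  if (length(y) == 0) stop("empty test set")
  pred <- stats::predict(model, as.matrix(x))
  y <- factor(y, levels = c("HC", "MDD"))
  pred <- factor(pred, levels = c("HC", "MDD"))
  tp <- sum(pred == "MDD" & y == "MDD")
  fn <- sum(pred == "HC" & y == "MDD")
  tn <- sum(pred == "HC" & y == "HC")
  fp <- sum(pred == "MDD" & y == "HC")
  list(
    accuracy = 100 * (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp)
  )
}

#' One pass of the modeling pipeline
#'
#' split -> z-score (training statistics) -> feature selection -> grid search
#' with stratified CV -> final fit -> test evaluation.
#'
#' @param tab Unstandardized `feature_table`.
#' @param config A [run_config()].
#' @param route `"ttest"` or `"auc"`.
#' @param k Feature count for the AUC route (required when `route = "auc"`).
#' @param folds CV folds (default 10).
#' @param seed Integer seed (drives the split and fold shuffles).
#' @param features Optional fixed feature set; skips selection when given.
#' @return List with the selected features, best hyperparameters, CV and test
#'   performance.
#' @export
run_pipeline_once <- function(tab, config = run_config(),
                              route = c("ttest", "auc"), k = NULL,
                              folds = 10, seed = config$seed,
                              features = NULL) {
  route <- match.arg(route)
  sp <- split_table(tab, config$train_fraction, seed = seed,
                    unit = config$split_unit)
  z <- suppressWarnings(zscore_tables(sp$train, sp$test))
  if (is.null(features)) {
    sel <- if (route == "ttest") {
      suppressWarnings(ttest_select(z$train, config$selection_alpha))
    } else {
      if (is.null(k)) stop("the AUC route needs k")
      auc_rank_select(z$train, min(k, length(feature_names(z$train))))
    }
    features <- sel$selected
    if (length(features) == 0) {
      # nothing survives the filter: fall back to the single best statistic
      stat <- sel$statistic
      features <- names(stat)[order(if (route == "ttest") stat else -stat)][1]
    }
  } else {
    sel <- NULL
    features <- intersect(features, feature_names(z$train))
  }
  xtr <- feature_matrix(z$train)[, features, drop = FALSE]
  xte <- feature_matrix(z$test)[, features, drop = FALSE]
  gs <- grid_search(xtr, z$train$group, config$svm_grid, folds = folds,
                    seed = seed + 1L)
  fit <- e1071::svm(xtr, factor(z$train$group, c("HC", "MDD")),
                    type = "C-classification", kernel = "radial",
                    cost = gs$cost, gamma = gs$gamma, scale = FALSE)
  ev <- evaluate_model(fit, xte, z$test$group)
  list(features = features, n_features = length(features),
       selection = sel, cost = gs$cost, gamma = gs$gamma,
       cv_accuracy = 100 * gs$cv_accuracy,
       accuracy = ev$accuracy, sensitivity = ev$sensitivity,
       specificity = ev$specificity, seed = seed)
}

.ci_half_width <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(0)
  stats::qnorm(0.975) * stats::sd(x) / sqrt(length(x))
}

#' Repeated train/test evaluation
#'
#' Re-runs the full split -> standardize -> select -> grid-search -> evaluate
#' chain with fresh split seeds and aggregates the per-repeat rates as mean
#' with a 95% normal-approximation CI half-width. Both aggregation styles are
#' reported: the mean over repeats and the single best repeat.
#'
#' @inheritParams run_pipeline_once
#' @param n_repeats Number of repeats (default from config).
#' @return A `model_report`: list with `per_repeat` (data frame) and
#'   `aggregate`.
#' @export
repeat_experiment <- function(tab, config = run_config(),
                              route = c("ttest", "auc"), k = NULL,
                              folds = 10, n_repeats = config$n_repeats) {
  route <- match.arg(route)
  runs <- lapply(seq_len(n_repeats), function(i) {
    r <- run_pipeline_once(tab, config, route, k = k, folds = folds,
                           seed = config$seed + 7L * i)
    data.frame(repeat_index = i, n_features = r$n_features, cost = r$cost,
               gamma = r$gamma, cv_accuracy = r$cv_accuracy,
               accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity)
  })
  per <- do.call(rbind, runs)
  agg <- list(
    n_repeats = n_repeats,
    n_features = mean(per$n_features),
    cv_accuracy = mean(per$cv_accuracy),
    accuracy = mean(per$accuracy),
    accuracy_ci = .ci_half_width(per$accuracy),
    sensitivity = mean(per$sensitivity, na.rm = TRUE),
    sensitivity_ci = .ci_half_width(per$sensitivity),
    specificity = mean(per$specificity, na.rm = TRUE),
    specificity_ci = .ci_half_width(per$specificity),
    best_accuracy = max(per$accuracy)
  )
  structure(list(per_repeat = per, aggregate = agg, route = route),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  a <- x$aggregate
  cat("<model_report> route=", x$route, ", ", a$n_repeats, " repeats\n",
      sprintf("  accuracy    %.2f%% (CI %.2f)\n", a$accuracy, a$accuracy_ci),
      sprintf("  sensitivity %.2f%% (CI %.2f)\n", a$sensitivity, a$sensitivity_ci),
      sprintf("  specificity %.2f%% (CI %.2f)\n", a$specificity, a$specificity_ci),
      if (!is.null(x$permutation_p))
        sprintf("  permutation p = %.4f\n", x$permutation_p),
      sep = "")
  invisible(x)
}

# permute group labels at the subject level, keeping windows together
.shuffle_labels <- function(tab, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  subj <- unique(tab$subject_id)
  grp <- tab$group[match(subj, tab$subject_id)]
  new_grp <- sample(grp)
  tab$group <- new_grp[match(tab$subject_id, subj)]
  feature_table(as.data.frame(tab))
}

#' Label-permutation validity test
#'
#' Re-runs the full pipeline (selection included, unless
#' `refit_selection = FALSE`) on label-shuffled copies of the data and
#' compares the permuted test accuracies with the observed one. The p-value
#' uses the add-one estimator `(1 + #{permuted >= observed}) / (n + 1)`, so
#' it is never exactly zero.
#'
#' @inheritParams run_pipeline_once
#' @param n_permutations Number of label shuffles (default from config).
#' @param observed Observed test accuracy in percent; computed with
#'   [run_pipeline_once()] if missing.
#' @param refit_selection Re-run feature selection inside each permutation
#'   (default TRUE, the full-pipeline permutation); FALSE reuses the observed
#'   run's features.
#' @return List with `p_value`, `observed` and the permuted accuracies.
#' @export
permutation_test <- function(tab, config = run_config(),
                             route = c("ttest", "auc"), k = NULL,
                             folds = 10,
                             n_permutations = config$n_permutations,
                             observed = NULL, refit_selection = TRUE) {
  route <- match.arg(route)
  obs_run <- NULL
  if (is.null(observed)) {
    obs_run <- run_pipeline_once(tab, config, route, k = k, folds = folds,
                                 seed = config$seed)
    observed <- obs_run$accuracy
  }
  fixed <- if (!refit_selection) {
    if (is.null(obs_run)) {
      obs_run <- run_pipeline_once(tab, config, route, k = k, folds = folds,
                                   seed = config$seed)
    }
    obs_run$features
  }
  perm_acc <- vapply(seq_len(n_permutations), function(i) {
    shuffled <- .shuffle_labels(tab, seed = config$seed + 97L * i)
    r <- run_pipeline_once(shuffled, config, route, k = k, folds = folds,
                           seed = config$seed + 97L * i + 1L,
                           features = fixed)
    r$accuracy
  }, 0)
  p <- (1 + sum(perm_acc >= observed)) / (n_permutations + 1)
  list(p_value = p, observed = observed, permuted = perm_acc)
}
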