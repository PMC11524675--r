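## Filter-based feature selection: train/test splitting, z-scoring on the
## training statistics only, the pooled-variance t-test route and the
## AUC-ranking route, plus the incremental-feature-count sweep.

#' Split a feature table into training and test sets
#'
#' Random stratified split by group. With `unit = "subject"` (the default)
#' whole subjects are assigned to one side, so no subject's windows leak
#' across the split; `unit = "window"` splits rows directly.
#'
#' @param tab A `feature_table` with both classes present.
#' @param train_fraction Fraction assigned to training (default 0.8); per
#'   class, `round(fraction * n_units)` units go to training.
#' @param seed Integer seed.
#' @param unit `"subject"` or `"window"`.
#' @return List with elements `train` and `test` (feature tables).
#' @export
split_table <- function(tab, train_fraction = 0.8, seed = 1L,
                        unit = c("subject", "window")) {
  stopifnot(inherits(tab, "feature_table"))
  unit <- match.arg(unit)
  groups <- unique(tab$group)
  if (length(groups) < 2) {
    stop("feature table contains a single class (", groups,
         "); cannot form a stratified split")
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  train_rows <- logical(nrow(tab))
  for (g in groups) {
    if (unit == "subject") {
      subj <- unique(tab$subject_id[tab$group == g])
      n_tr <- round(train_fraction * length(subj))
      n_tr <- max(1, min(length(subj) - 1, n_tr))
      tr <- sample(subj, n_tr)
      train_rows[tab$group == g & tab$subject_id %in% tr] <- TRUE
    } else {
      idx <- which(tab$group == g)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- max(1, min(length(idx) - 1, n_tr))
      train_rows[sample(idx, n_tr)] <- TRUE
    }
  }
  list(train = feature_table(as.data.frame(tab)[train_rows, , drop = FALSE]),
       test = feature_table(as.data.frame(tab)[!train_rows, , drop = FALSE]))
}

#' Z-score standardization using training statistics
#'
#' Per-feature mean and population SD are estimated on the training rows only
#' and applied to both sets. Columns that are constant (or non-finite) in
#' training carry no usable information under this scaling and are dropped
#' from both sets with a warning; the dropped names are recorded in the
#' `"dropped"` attribute.
#'
#' @param train,test `feature_table` objects with identical feature columns.
#' @return List with standardized `train` and `test` tables (attribute
#'   `standardized` set), plus `center` and `scale` vectors.
#' @export
zscore_tables <- function(train, test) {
  fn <- feature_names(train)
  stopifnot(identical(fn, feature_names(test)))
  X <- feature_matrix(train)
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))   # population SD
  bad <- !is.finite(sigma) | sigma == 0 | !is.finite(mu)
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " constant or non-finite training column(s): ",
            paste(utils::head(fn[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ...")
  }
  keep <- fn[!bad]
  scale_tab <- function(tab) {
    df <- as.data.frame(tab)[, c("subject_id", "window_index", "group", keep),
                             drop = FALSE]
    df[keep] <- sweep(sweep(as.matrix(df[keep]), 2, mu[!bad]), 2,
                      sigma[!bad], "/")
    out <- feature_table(df)
    attr(out, "standardized") <- TRUE
    out
  }
  out <- list(train = scale_tab(train), test = scale_tab(test),
              center = mu[!bad], scale = sigma[!bad])
  attr(out, "dropped") <- fn[bad]
  out
}

.selection_result <- function(route, statistic, selected, params) {
  structure(list(route = route, statistic = statistic,
                 selected = selected, params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> route=", x$route, ": ", length(x$selected), "/",
      length(x$statistic), " features selected\n", sep = "")
  invisible(x)
}

#' t-test feature selection
#'
#' Per-feature two-sample Student's t-test (pooled variance) between the MDD
#' and HC training rows; features with two-sided p below `alpha` are
#' selected. Columns whose pooled variance is zero have no defined p-value
#' and are skipped with a warning.
#'
#' @param train Training `feature_table` (both classes present).
#' @param alpha Significance level (default 0.05).
#' @return A `selection_result` whose `statistic` holds the p-values.
#' @export
ttest_select <- function(train, alpha = 0.05) {
  X <- feature_matrix(train)
  g <- train$group
  if (length(unique(g)) < 2) stop("both classes required")
  i1 <- g == "MDD"; i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per class")
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2, stats::var)
  v2 <- apply(X[i2, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- rep(NA_real_, ncol(X))
  ok <- is.finite(se) & se > 0
  tstat <- (m1[ok] - m2[ok]) / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  names(p) <- colnames(X)
  if (any(!ok)) {
    warning(sum(!ok), " column(s) with undefined t statistic skipped")
  }
  selected <- names(p)[!is.na(p) & p < alpha]
  .selection_result("ttest", p, selected, list(alpha = alpha))
}

# per-column AUC via the rank-sum (Mann-Whitney) construction, MDD = positive
.column_auc <- function(X, positive) {
  n1 <- sum(positive); n2 <- sum(!positive)
  apply(X, 2, function(x) {
    r <- rank(x, ties.method = "average")
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
}

#' AUC-ranking feature selection
#'
#' Each feature's AUC for discriminating MDD from HC is computed with the
#' Mann-Whitney rank construction; the ranking statistic is `|AUC - 0.5|`
#' (0.5 = perfect separation in either direction, 0 = chance) and the `k`
#' largest are selected (ties broken by column order).
#'
#' @param train Training `feature_table`.
#' @param k Number of features to keep.
#' @return A `selection_result` whose `statistic` holds `|AUC - 0.5|`.
#' @export
auc_rank_select <- function(train, k) {
  X <- feature_matrix(train)
  if (k < 1 || k > ncol(X)) {
    stop("k must lie in 1..", ncol(X), " (got ", k, ")")
  }
  g <- train$group
  if (length(unique(g)) < 2) stop("both classes required")
  auc <- .column_auc(X, g == "MDD")
  stat <- abs(auc - 0.5)
  names(stat) <- colnames(X)
  ord <- order(stat, decreasing = TRUE)
  selected <- colnames(X)[sort(ord[seq_len(k)])]
  .selection_result("auc", stat, selected, list(k = k))
}

#' Accuracy curve over increasing feature counts
#'
#' Features are ranked once on the training set by `|AUC - 0.5|`; for each
#' candidate count `k` the top-k features are evaluated with the SVM over
#' three random inner train/test splits and the accuracies averaged. The
#' chosen `k*` is the smallest k whose accuracy reaches at least 95% of the
#' curve's maximum and gains no more than one accuracy point over the next
#' three grid points (an explicit reading of "the turning point at which the
#' curve plateaus").
#'
#' @param train Standardized training `feature_table`.
#' @param k_grid Ascending feature counts to evaluate.
#' @param config A [run_config()]; its `svm_grid` is used at each k.
#' @param folds CV folds inside the grid search (default 3 for speed).
#' @param n_inner Number of inner evaluation splits (default 3).
#' @param seed Integer seed.
#' @return List with `k_star`, `curve` (data.frame k, accuracy) and the
#'   ranked feature order.
#' @export
sweep_k <- function(train, k_grid, config = run_config(), folds = 3,
                    n_inner = 3, seed = 1L) {
  stopifnot(all(diff(k_grid) > 0))
  X <- feature_matrix(train)
  auc <- .column_auc(X, train$group == "MDD")
  ord <- order(abs(auc - 0.5), decreasing = TRUE)
  ranked <- colnames(X)[ord]
  acc <- vapply(seq_along(k_grid), function(i) {
    keep <- ranked[seq_len(min(k_grid[i], length(ranked)))]
    inner <- vapply(seq_len(n_inner), function(r) {
      sp <- split_table(train, config$train_fraction,
                        seed = seed + 131L * r + i, unit = config$split_unit)
      gs <- grid_search(feature_matrix(sp$train)[, keep, drop = FALSE],
                        sp$train$group, config$svm_grid, folds = folds,
                        seed = seed + r)
      fit <- e1071::svm(feature_matrix(sp$train)[, keep, drop = FALSE],
                        factor(sp$train$group, c("HC", "MDD")),
                        type = "C-classification", kernel = "radial",
                        cost = gs$cost, gamma = gs$gamma, scale = FALSE)
      evaluate_model(fit, feature_matrix(sp$test)[, keep, drop = FALSE],
                     sp$test$group)$accuracy
    }, 0)
    mean(inner)
  }, 0)
  peak <- max(acc)
  k_star <- k_grid[length(k_grid)]
  for (i in seq_along(k_grid)) {
    ahead <- acc[seq(i + 1, min(i + 3, length(acc)))]
    if (i == length(k_grid)) ahead <- acc[i]
    if (acc[i] >= 0.95 * peak && all(ahead - acc[i] <= 1)) {
      k_star <- k_grid[i]
      break
    }
  }
  list(k_star = k_star, curve = data.frame(k = k_grid, accuracy = acc),
       ranking = ranked)
}
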