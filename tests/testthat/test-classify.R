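test_that("the published hyperparameter grid has 101 x 101 candidates", {
  cand <- grid_candidates(svm_grid())
  expect_equal(nrow(cand), 101 * 101)
  expect_equal(range(cand$c_exp), c(-10, 10))
  expect_equal(range(cand$g_exp), c(-10, 10))
  # tie-break ordering: cost ascending, then gamma
  expect_true(!is.unsorted(cand$c_exp))
  expect_equal(cand$g_exp[1:2], c(-10, -9.8))
})

test_that("grid search solves separable blobs and is deterministic", {
  set.seed(1)
  n <- 30
  x <- rbind(matrix(rnorm(2 * n, -3), ncol = 2),
             matrix(rnorm(2 * n, 3), ncol = 2))
  y <- rep(c("HC", "MDD"), each = n)
  g <- svm_grid(c(-3, 3), c(-3, 3), 1.5)
  gs <- grid_search(x, y, g, folds = 10, seed = 4)
  expect_gte(gs$cv_accuracy, 0.95)
  gs2 <- grid_search(x, y, g, folds = 10, seed = 4)
  expect_identical(gs[c("cost", "gamma", "cv_accuracy")],
                   gs2[c("cost", "gamma", "cv_accuracy")])

  single <- svm_grid(c(0, 0.1), c(0, 0.1), 1)
  gs3 <- grid_search(x, y, single, folds = 5, seed = 1)
  expect_equal(gs3$c_exp, 0)
  expect_equal(gs3$g_exp, 0)
})

test_that("folds shrink with a warning when a class is small", {
  set.seed(2)
  x <- matrix(rnorm(24), ncol = 2)
  y <- rep(c("HC", "MDD"), each = 6)
  expect_warning(gs <- grid_search(x, y, svm_grid(c(0, 1), c(0, 1), 1),
                                   folds = 10, seed = 1),
                 "reducing folds")
  expect_true(is.finite(gs$cv_accuracy))
})

test_that("evaluation reports confusion-derived rates with MDD positive", {
  # counts 3 TP, 1 FN, 4 TN, 0 FP -> 87.5 / 75 / 100
  fake <- structure(list(), class = "fake_clf")
  predict.fake_clf <<- function(object, newdata, ...) {
    factor(c("MDD", "MDD", "MDD", "HC", "HC", "HC", "HC", "HC"),
           levels = c("HC", "MDD"))
  }
  on.exit(rm(predict.fake_clf, envir = globalenv()), add = TRUE)
  y <- c("MDD", "MDD", "MDD", "MDD", "HC", "HC", "HC", "HC")
  ev <- evaluate_model(fake, matrix(0, 8, 1), y)
  expect_equal(ev$accuracy, 87.5)
  expect_equal(ev$sensitivity, 75)
  expect_equal(ev$specificity, 100)

  predict.fake_clf <<- function(object, newdata, ...) {
    factor(rep("MDD", 8), levels = c("HC", "MDD"))
  }
  ev2 <- evaluate_model(fake, matrix(0, 8, 1), y)
  expect_equal(ev2$accuracy, 50)
  expect_equal(ev2$sensitivity, 100)
  expect_equal(ev2$specificity, 0)

  ev3 <- evaluate_model(fake, matrix(0, 8, 1), rep("MDD", 8))
  expect_true(is.na(ev3$specificity))
})

test_that("repeat_experiment aggregates and is reproducible", {
  tab <- gaussian_table(12, 10, shift = 1.2, seed = 3)
  cfg <- run_config(svm_grid = svm_grid(c(-2, 2), c(-2, 2), 2),
                    seed = 5, split_unit = "subject")
  rep1 <- repeat_experiment(tab, cfg, "ttest", folds = 5, n_repeats = 1)
  expect_equal(rep1$aggregate$accuracy_ci, 0)
  expect_equal(rep1$aggregate$accuracy, rep1$per_repeat$accuracy[1])

  rep3a <- repeat_experiment(tab, cfg, "ttest", folds = 5, n_repeats = 3)
  rep3b <- repeat_experiment(tab, cfg, "ttest", folds = 5, n_repeats = 3)
  expect_identical(rep3a$per_repeat, rep3b$per_repeat)
  expect_gte(rep3a$aggregate$best_accuracy, rep3a$aggregate$accuracy)
})

test_that("the AUC route trains on exactly k features", {
  tab <- gaussian_table(12, 10, shift = 1, seed = 4)
  cfg <- run_config(svm_grid = svm_grid(c(-2, 2), c(-2, 2), 2), seed = 2,
                    split_unit = "subject")
  r <- run_pipeline_once(tab, cfg, "auc", k = 4, folds = 5)
  expect_equal(r$n_features, 4)
  expect_error(run_pipeline_once(tab, cfg, "auc", folds = 5), "needs k")
})

test_that("permutation p-values take their theoretical values at n = 1", {
  tab <- gaussian_table(10, 6, shift = 2, seed = 6)
  cfg <- run_config(svm_grid = svm_grid(c(-1, 1), c(-1, 1), 1), seed = 3,
                    split_unit = "subject")
  pt <- permutation_test(tab, cfg, "ttest", folds = 3, n_permutations = 1)
  expect_true(pt$p_value %in% c(1 / 2, 1))
})

test_that("a strong group effect yields a small permutation p", {
  tab <- gaussian_table(14, 8, shift = 2.5, seed = 7)
  cfg <- run_config(svm_grid = svm_grid(c(-2, 2), c(-2, 2), 2), seed = 8,
                    split_unit = "subject")
  pt <- permutation_test(tab, cfg, "ttest", folds = 5, n_permutations = 24)
  expect_equal(pt$observed, 100)
  expect_lt(pt$p_value, 0.05)
})
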