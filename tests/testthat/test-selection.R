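test_that("subject-level splits are stratified, seeded and leak-free", {
  tab <- gaussian_table(21, 10, seed = 2)
  sp <- split_table(tab, 0.8, seed = 3, unit = "subject")
  n_train <- length(unique(sp$train$subject_id))
  n_test <- length(unique(sp$test$subject_id))
  expect_equal(n_train, 34)   # round(0.8 * 21) per class
  expect_equal(n_test, 8)
  expect_length(intersect(unique(sp$train$subject_id),
                          unique(sp$test$subject_id)), 0)
  expect_setequal(unique(sp$train$group), c("MDD", "HC"))

  sp2 <- split_table(tab, 0.8, seed = 3, unit = "subject")
  expect_identical(sp$train$subject_id, sp2$train$subject_id)

  all_hc <- feature_table(transform(as.data.frame(tab), group = "HC"))
  expect_error(split_table(all_hc, 0.8, seed = 1), "single class")
})

test_that("z-scoring uses training statistics only (population SD)", {
  df <- data.frame(subject_id = c("a", "b", "c", "d", "e"),
                   window_index = 1L,
                   group = c("MDD", "MDD", "MDD", "HC", "HC"),
                   x = c(1, 2, 3, 10, 20),
                   check.names = FALSE)
  train <- feature_table(df[1:3, ])
  test <- feature_table(df[4:5, ])
  z <- zscore_tables(train, test)
  expect_equal(feature_matrix(z$train)[, "x"],
               c(-1.224745, 0, 1.224745), tolerance = 1e-6,
               ignore_attr = TRUE)
  # test rows transformed with the train mean 2 and population SD sqrt(2/3)
  expect_equal(feature_matrix(z$test)[, "x"],
               (c(10, 20) - 2) / sqrt(2 / 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("constant training columns are dropped and recorded", {
  tab <- gaussian_table(5, 3, seed = 4)
  tab$f002 <- 7
  tab <- feature_table(as.data.frame(tab))
  sp <- split_table(tab, 0.8, seed = 1)
  expect_warning(z <- zscore_tables(sp$train, sp$test), "f002")
  expect_false("f002" %in% feature_names(z$train))
  expect_equal(attr(z, "dropped"), "f002")
})

test_that("t-test selection matches the closed-form pooled-variance oracle", {
  tab <- gaussian_table(15, 40, shift = 0.3, seed = 6)
  sel <- ttest_select(tab, alpha = 0.05)
  X <- feature_matrix(tab)
  for (j in sample(ncol(X), 10)) {
    want <- t.test(X[tab$group == "MDD", j], X[tab$group == "HC", j],
                   var.equal = TRUE)$p.value
    expect_equal(unname(sel$statistic[j]), want, tolerance = 1e-10)
  }
  expect_true(all(sel$statistic[sel$selected] < 0.05))
})

test_that("t-test selection handles huge effects and degenerate alphas", {
  tab <- gaussian_table(21, 5, seed = 7)
  tab$f001 <- tab$f001 + ifelse(tab$group == "MDD", 5, 0)
  tab <- feature_table(as.data.frame(tab))
  expect_true("f001" %in% ttest_select(tab, 0.05)$selected)
  expect_length(ttest_select(tab, alpha = 0)$selected, 0)
})

test_that("per-feature AUC equals brute-force pair counting", {
  set.seed(8)
  tab <- gaussian_table(12, 8, shift = 0.5, seed = 8)
  sel <- auc_rank_select(tab, k = 3)
  X <- feature_matrix(tab)
  pos <- tab$group == "MDD"
  for (j in seq_len(ncol(X))) {
    expect_equal(unname(sel$statistic[j]),
                 abs(auc_oracle(X[, j], pos) - 0.5))
  }
  # ties handled: integer-valued column
  xt <- sample(1:3, nrow(tab), replace = TRUE)
  expect_equal(abs(auc_oracle(xt, pos) - 0.5),
               unname(abs(resteeg:::.column_auc(cbind(x = xt), pos) - 0.5)))
})

test_that("AUC ranking prefers a perfect separator and is rank-invariant", {
  tab <- gaussian_table(10, 4, seed = 9)
  tab$f001 <- ifelse(tab$group == "MDD", 1, 0) + seq_len(nrow(tab)) * 1e-9
  tab <- feature_table(as.data.frame(tab))
  sel <- auc_rank_select(tab, 1)
  expect_equal(sel$selected, "f001")
  expect_equal(max(sel$statistic), 0.5)

  # monotone transform leaves the statistic unchanged
  tab2 <- tab
  tab2$f002 <- exp(tab2$f002)
  sel2 <- auc_rank_select(feature_table(as.data.frame(tab2)), 1)
  expect_equal(sel2$statistic["f002"], sel$statistic["f002"])

  expect_error(auc_rank_select(tab, 99), "k must lie")
})

test_that("the feature-count sweep returns a full curve and a small k*", {
  tab <- gaussian_table(15, 12, shift = 1.5, seed = 10)
  cfg <- run_config(svm_grid = svm_grid(c(-2, 2), c(-2, 2), 2),
                    split_unit = "subject", seed = 1)
  sw <- sweep_k(tab, k_grid = c(1, 2, 4, 8), config = cfg, folds = 3,
                n_inner = 2, seed = 1)
  expect_equal(nrow(sw$curve), 4)
  expect_lte(sw$k_star, 8)

  sw1 <- sweep_k(tab, k_grid = 1, config = cfg, folds = 3, n_inner = 2)
  expect_equal(sw1$k_star, 1)
  expect_equal(nrow(sw1$curve), 1)
})

test_that("assembling blocks with mismatched sample units fails", {
  a <- gaussian_table(4, 3, seed = 11)
  b <- gaussian_table(4, 3, seed = 12)
  names(b)[4:6] <- c("g001", "g002", "g003")
  b <- feature_table(as.data.frame(b))
  combined <- assemble(a, b)
  expect_length(feature_names(combined), 6)

  c_bad <- feature_table(as.data.frame(b)[c(2:nrow(b), 1), ])
  expect_error(assemble(a, c_bad), "mismatched")
})

test_that("extracted cohort tables carry the expected feature blocks", {
  tab <- small_cohort_table()
  fn <- feature_names(tab)
  # 6 channels, 5 bands: relpow 30, asym 3, coh 3x3x5 = 45, net 15,
  # sampen/mse/dfa 30 each
  expect_length(grep("^relpow:", fn), 30)
  expect_length(grep("^asym:alpha:", fn), 3)
  expect_length(grep("^coh:", fn), 45)
  expect_length(grep("^net:", fn), 15)
  expect_length(grep("^sampen:", fn), 30)
  expect_length(grep("^mse:", fn), 30)
  expect_length(grep("^dfa:", fn), 30)
  # one row per subject and window
  expect_equal(nrow(tab), 8 * 5)
  expect_true(all(table(tab$subject_id) == 5))
})
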