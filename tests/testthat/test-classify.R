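test_that("confusion metrics match their formulas and a brute-force recount", {
  perfect <- confusion_metrics(50, 0, 50, 0)
  expect_identical(unname(perfect), rep(100, 5))
  m <- confusion_metrics(9, 1, 8, 2)
  expect_equal(unname(m["Se"]), 90)
  expect_equal(unname(m["Sp"]), 80)
  expect_equal(unname(m["Ac"]), 85)
  expect_equal(unname(m["Pr"]), 900 / 11, tolerance = 1e-12)
  expect_equal(unname(m["Fs"]), 2 * (900 / 11) * 90 / (900 / 11 + 90),
               tolerance = 1e-12)
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
  # undefined ratios are NA, not zero
  expect_true(is.na(confusion_metrics(0, 0, 5, 5)["Se"]))

  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    pred <- sample(c("rest", "task"), n, replace = TRUE)
    truth <- sample(c("rest", "task"), n, replace = TRUE)
    cts <- confusion_oracle(pred, truth)
    if (sum(cts) == 0) next
    got <- confusion_metrics(cts["tp"], cts["fn"], cts["tn"], cts["fp"])
    expect_equal(unname(got["Ac"]),
                 100 * mean(pred == truth), tolerance = 1e-12)
  }
})

test_that("ROC/AUC handle perfect, inverted, tied and random scores", {
  y <- rep(c("rest", "task"), each = 10)
  expect_equal(roc_auc(c(1:10, 11:20), y)$auc, 1)
  expect_equal(roc_auc(c(11:20, 1:10), y)$auc, 0)
  expect_equal(roc_auc(rep(0.5, 20), y)$auc, 0.5)
  expect_error(roc_auc(1:5, rep("task", 5)), "both classes")
  set.seed(42)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    y <- sample(c("rest", "task"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(s, y)$auc, auc_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("fold assignment is a stratified partition; grouped CV keeps subjects together", {
  df <- make_feature_df(n = 100, effect = 10)
  cv <- stratified_kfold_cv(model_spec("lda"), df, k = 10, seed = 2)
  expect_identical(sort(unique(cv$fold)), 1:10)
  expect_identical(tabulate(cv$fold), rep(10L, 10))
  for (f in 1:10) {
    tab <- table(df$condition[cv$fold == f])
    expect_lte(abs(tab["task"] - tab["rest"]), 1)
  }
  # each row scored exactly once out of fold: predictions defined everywhere
  expect_false(anyNA(cv$scores))

  cvg <- stratified_kfold_cv(model_spec("lda"), df, k = 5, seed = 2,
                             group_by_subject = TRUE)
  for (s in unique(df$subject_id))
    expect_length(unique(cvg$fold[df$subject_id == s]), 1)
})

test_that("separable data is classified perfectly; shuffled labels sit at chance", {
  df <- make_feature_df(n = 100, effect = 10)
  # midpoint-splitting trees separate the 10-sigma Gaussians exactly
  cvb <- stratified_kfold_cv(model_spec("bagged_trees"), df, k = 10, seed = 1)
  expect_equal(cvb$mean_accuracy, 100)
  expect_equal(cvb$auc, 1)
  # gradient boosting places splits at the training class boundary, so the
  # held-out class-extreme point can fall on the wrong side: at most 1 error
  cv <- stratified_kfold_cv(model_spec("boosted_trees"), df, k = 10, seed = 1)
  expect_gte(cv$mean_accuracy, 99)
  expect_gte(cv$auc, 0.99)

  accs <- vapply(1:10, function(s) {
    dfs <- make_feature_df(n = 100, effect = 0, seed = 100 + s)
    stratified_kfold_cv(model_spec("lda"), dfs, k = 5,
                        seed = s)$mean_accuracy
  }, numeric(1))
  expect_true(all(accs >= 30 & accs <= 70))
  expect_gte(mean(accs), 40)
  expect_lte(mean(accs), 60)
})

test_that("normalization statistics never leak from the test fold", {
  df <- make_feature_df(n = 60, effect = 2)
  cv1 <- stratified_kfold_cv(model_spec("lda"), df, k = 5, seed = 9)
  # corrupt the rows of fold 3 and refit: every other fold's training set
  # changes, but fold 3's own training statistics must be identical
  df2 <- df
  rows <- which(cv1$fold == 3)
  for (cn in setdiff(colnames(df2), c("condition", "subject_id")))
    df2[rows, cn] <- df2[rows, cn] * 1000 + 5
  cv2 <- stratified_kfold_cv(model_spec("lda"), df2, k = 5, seed = 9)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$norm_ranges[[3]], cv2$norm_ranges[[3]])
})

test_that("cross-validation is deterministic given the seed", {
  df <- make_feature_df(n = 80, effect = 1)
  a <- stratified_kfold_cv(model_spec("boosted_trees"), df, k = 5, seed = 4)
  b <- stratified_kfold_cv(model_spec("boosted_trees"), df, k = 5, seed = 4)
  expect_identical(a$fold, b$fold)
  expect_identical(a$scores, b$scores)
  expect_identical(a$metrics, b$metrics)
})

test_that("every classifier family fits, predicts, and beats chance on separable data", {
  df <- make_feature_df(n = 60, effect = 6)
  for (fam in c("boosted_trees", "bagged_trees", "subspace_knn",
                "subspace_discriminant", "svm_linear", "svm_quadratic",
                "svm_cubic", "svm_rbf", "knn", "naive_bayes", "lda", "qda",
                "logistic", "tree")) {
    cv <- suppressWarnings(
      stratified_kfold_cv(model_spec(fam), df, k = 3, seed = 5))
    expect_gte(cv$mean_accuracy, 80)
  }
  expect_error(model_spec("deep_net"), "arg")
  expect_error(model_spec("knn", list(bogus = 1)), "bogus")
})

test_that("permutation test follows the add-one rule and rejects on real effects", {
  df <- make_feature_df(n = 60, effect = 8)
  pt <- permutation_test(model_spec("lda"), df, n_perm = 19, k = 3, seed = 6)
  expect_gt(pt$p_value, 0)
  expect_equal(pt$p_value, (1 + sum(pt$permuted >= pt$observed)) / 20)
  expect_equal(pt$p_value, 1 / 20)   # no permutation ties a strong effect
  expect_error(permutation_test(model_spec("lda"), df, n_perm = 0), "n_perm")
})

test_that("learning curves have the right shape and more data does not hurt", {
  df <- make_feature_df(n = 80, effect = 6)
  lc <- learning_curve(model_spec("lda"), df,
                       fractions = c(0.1, 0.25, 0.5, 0.75, 1), k = 4,
                       seed = 7, repeats = 2)
  expect_identical(dim(lc), c(5L, 3L))
  # averaged over seeds, full data is at least as good as 10%
  vals <- vapply(1:5, function(s) {
    l <- learning_curve(model_spec("lda"), df, fractions = c(0.1, 1), k = 4,
                        seed = 20 + s, repeats = 1)
    l$validation_accuracy[2] - l$validation_accuracy[1]
  }, numeric(1))
  expect_gte(mean(vals), 0)
  expect_error(learning_curve(model_spec("lda"), df, fractions = 1.5),
               "fractions")
})

test_that("Bayesian optimization improves monotonically and respects its budget", {
  df <- make_feature_df(n = 60, effect = 2, seed = 3)
  bo1 <- bayesian_optimize("knn", df, budget = 1, seed = 8, k_inner = 3)
  expect_identical(nrow(bo1$history), 1L)
  bo <- bayesian_optimize("knn", df, budget = 8, seed = 8, k_inner = 3)
  expect_identical(nrow(bo$history), 8L)
  expect_true(!is.unsorted(bo$history$running_best))
  expect_equal(bo$best_objective, max(bo$history$objective))
  expect_error(bayesian_optimize("lda", df), "search space")

  # tuned boosted trees do not fall more than a point below the default
  diffs <- vapply(1:5, function(s) {
    dfs <- make_feature_df(n = 60, effect = 1.5, seed = 50 + s)
    tuned <- bayesian_optimize("boosted_trees", dfs, budget = 5,
                               seed = s, k_inner = 3)
    base <- stratified_kfold_cv(model_spec("boosted_trees"), dfs, k = 3,
                                seed = emfdeeg:::derive_seed(s, "bo-inner"))
    tuned$best_objective - base$mean_accuracy
  }, numeric(1))
  expect_true(all(diffs >= -1))
})
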