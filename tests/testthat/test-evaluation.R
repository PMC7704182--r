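test_that("stratified folds balance both the classes and the totals", {
  labels <- c(rep(1L, 23), rep(-1L, 16))
  for (s in 1:10) {
    f <- stratified_folds(labels, 3, seed = s)
    expect_setequal(unique(f), 1:3)
    sizes <- tabulate(f, 3)
    expect_true(all(sizes == 13))
    pos <- tabulate(f[labels == 1L], 3)
    neg <- tabulate(f[labels == -1L], 3)
    expect_true(all(pos %in% c(7L, 8L)))
    expect_true(all(neg %in% c(5L, 6L)))
  }
  expect_identical(stratified_folds(labels, 3, seed = 4),
                   stratified_folds(labels, 3, seed = 4))
  # leave-one-out via the unstratified path: n singleton folds
  loo <- stratified_folds(labels, length(labels), seed = 1, stratify = FALSE)
  expect_setequal(loo, seq_along(labels))
  expect_error(stratified_folds(labels, 17, seed = 1), "class")
})

test_that("rank-formulation AUC matches brute-force pair counting", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    labels <- sample(c(rep(1L, 2), rep(-1L, 2),
                       sample(c(-1L, 1L), n - 4, replace = TRUE)))
    scores <- if (i %% 2) rnorm(n) else sample(0:3, n, replace = TRUE) / 2
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC endpoints and canonical AUC cases are exact", {
  expect_equal(roc_auc(c(-1, -1, 1, 1), c(-1, -1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(1, -1, 1, -1, 1, -1))$auc, 0.5)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(-1, -1, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("confusion-matrix metrics follow their definitions exactly", {
  expect_equal(sens_spec(c(1, 1, -1, -1), c(1, 1, -1, -1)),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(unname(sens_spec(rep(1, 6), c(1, 1, -1, -1, -1, -1))[1:2]),
               c(1, 0))
  # at the study's group sizes: 1 FN among 23, 1 FP among 16
  truth <- c(rep(1, 23), rep(-1, 16))
  pred <- truth; pred[1] <- -1; pred[24] <- 1
  m <- sens_spec(pred, truth)
  expect_equal(unname(m["sensitivity"]), 22 / 23)
  expect_equal(unname(m["specificity"]), 15 / 16)
  expect_error(sens_spec(c(0, 1), c(1, -1)), "-1/\\+1")

  # pooled accuracy identity at arbitrary confusion matrices
  set.seed(3)
  for (i in 1:20) {
    n_pos <- sample(3:20, 1); n_neg <- sample(3:20, 1)
    truth <- c(rep(1, n_pos), rep(-1, n_neg))
    pred <- sample(c(-1, 1), n_pos + n_neg, replace = TRUE)
    m <- sens_spec(pred, truth)
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * n_pos + m[["specificity"]] * n_neg) /
                   (n_pos + n_neg), tolerance = 1e-12)
  }
})

test_that("repeated CV scores every subject once per repeat and is reproducible", {
  toy <- make_toy_cohort(n_pos = 14, n_neg = 10, d_inf = 2, d_noise = 4,
                         gap = 2, seed = 31)
  cfg <- blsvm_config(n_layers = 2, nodes_per_layer = 2, seed = 1)
  ev <- eval_config(folds = 3, repeats = 5, seed = 9)
  rep1 <- repeated_cv(toy$table, toy$labels, cfg, ev)
  expect_identical(nrow(rep1$per_repeat), 5L)
  expect_true(all(rep1$per_repeat$auc >= 0 & rep1$per_repeat$auc <= 1))
  # every subject in exactly one test fold per repeat
  for (r in 1:5) {
    f <- rep1$fold_assignments[, r]
    expect_true(all(f %in% 1:3))
    expect_false(anyNA(rep1$scores[, r]))
  }
  # pooled accuracy identity holds within each repeat
  n_pos <- sum(toy$labels == 1); n_neg <- sum(toy$labels == -1)
  expect_equal(rep1$per_repeat$accuracy,
               (rep1$per_repeat$sensitivity * n_pos +
                  rep1$per_repeat$specificity * n_neg) / (n_pos + n_neg),
               tolerance = 1e-12)
  # bit-identical regeneration from the master seed
  rep2 <- repeated_cv(toy$table, toy$labels, cfg, ev)
  expect_identical(rep1$per_repeat, rep2$per_repeat)
  expect_identical(rep1$scores, rep2$scores)
})

test_that("the published protocol shape is honoured: 50 repeats of 3 folds", {
  toy <- make_toy_cohort(n_pos = 14, n_neg = 10, d_inf = 2, d_noise = 2,
                         gap = 3, seed = 32)
  rep50 <- repeated_cv(toy$table, toy$labels,
                       blsvm_config(n_layers = 1, nodes_per_layer = 2, seed = 1),
                       eval_config(folds = 3, repeats = 50, seed = 2))
  expect_identical(nrow(rep50$per_repeat), 50L)
  expect_length(unique(rep50$per_repeat$repeat_id), 50L)
  expect_identical(rownames(rep50$summary),
                   c("auc", "sensitivity", "specificity", "accuracy"))
})

test_that("nested RFE inside folds yields a valid evaluation", {
  toy <- make_toy_cohort(n_pos = 14, n_neg = 12, d_inf = 2, d_noise = 6,
                         gap = 3, seed = 33)
  ev <- eval_config(folds = 2, repeats = 2, nested_selection = TRUE,
                    rfe = rfe_config(cv_folds = 2, cv_repeats = 1), seed = 5)
  rep <- repeated_cv(toy$table, toy$labels,
                     blsvm_config(n_layers = 1, nodes_per_layer = 2, seed = 1),
                     ev)
  expect_identical(nrow(rep$per_repeat), 2L)
  expect_gte(mean(rep$per_repeat$auc), 0.7)  # real signal survives nesting
})
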