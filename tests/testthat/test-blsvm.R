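test_that("a symmetric two-point problem is solved with zero bias", {
  X <- matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "f"))
  nd <- svm_node(X, c(-1, 1), kernel = "linear", cost = 1000)
  dec <- node_decision(nd, X)
  expect_identical(sign(dec), c(-1, 1))
  expect_lt(abs(node_decision(nd, matrix(0, 1, 1))), 1e-6)
  # support vectors of both classes sit on the margin
  expect_true(all(abs(abs(dec) - 1) < 1e-6))
})

test_that("the RBF kernel separates XOR where no linear rule can", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  y <- c(-1, -1, 1, 1)
  nd <- svm_node(X, y, kernel = "rbf", cost = 100, gamma = 1)
  expect_identical(sign(node_decision(nd, X)), as.numeric(y))
})

test_that("confidences are the tanh of the decision value, odd and bounded", {
  toy <- make_toy_cohort(seed = 21)
  nd <- svm_node(toy$values, toy$labels)
  dec <- node_decision(nd, toy$values)
  conf <- node_confidence(nd, toy$values)
  expect_equal(conf, tanh(dec), tolerance = 1e-12)
  expect_true(all(conf > -1 & conf < 1))
  expect_identical(sign(conf), sign(dec))
  expect_equal(tanh(2), 0.964027580075817, tolerance = 1e-12)
  expect_error(node_decision(nd, toy$values[, 1:3]), "dimension")
})

test_that("input augmentation concatenates layer-major confidence blocks", {
  x0 <- matrix(rnorm(26), 1, 26)
  confs <- list(rep(0.1, 8), rep(-0.2, 8))
  expect_identical(ncol(augment_input(x0, confs)), 26L + 2L * 8L)
  expect_identical(augment_input(x0), x0)
  padded <- augment_input(x0, list(rep(0, 8)))
  expect_equal(padded[1, 1:26], x0[1, ])
  expect_true(all(padded[1, 27:34] == 0))
  expect_error(augment_input(x0, list(rep(0, 8), rep(0, 5))), "ragged")
})

test_that("the fitted architecture obeys the dimension law", {
  toy <- make_toy_cohort(seed = 22)
  cfg <- blsvm_config(n_layers = 5, nodes_per_layer = 8, seed = 1)
  model <- blsvm(toy$table, toy$labels, cfg)
  dims <- node_input_dims(model)
  expect_identical(dim(dims), c(5L, 8L))
  d <- ncol(toy$values)
  for (l in 1:5) expect_true(all(dims[l, ] == d + (l - 1) * 8))
})

test_that("the degenerate 1x1 architecture without bootstrap is a plain SVM", {
  toy <- make_toy_cohort(n_pos = 15, n_neg = 15, seed = 23)
  cfg <- blsvm_config(n_layers = 1, nodes_per_layer = 1, bootstrap = FALSE,
                      seed = 1)
  model <- blsvm(toy$table, toy$labels, cfg)
  pred <- predict(model, toy$table)

  Z <- scale(toy$values)
  Z <- matrix(as.numeric(Z), nrow(Z), ncol(Z), dimnames = dimnames(toy$values))
  # same sd convention as the model (stats::sd), so Z matches exactly
  nd <- svm_node(Z, toy$labels, kernel = "rbf", cost = 1)
  expect_equal(pred$scores, tanh(node_decision(nd, Z)), tolerance = 1e-8)
  expect_identical(pred$labels, ifelse(pred$scores > 0, 1L, -1L))
})

test_that("fitting is deterministic and predictions stay inside [-1, 1]", {
  toy <- make_toy_cohort(seed = 24)
  hold <- make_toy_cohort(seed = 25)
  cfg <- blsvm_config(n_layers = 3, nodes_per_layer = 4, seed = 77)
  m1 <- blsvm(toy$table, toy$labels, cfg)
  m2 <- blsvm(toy$table, toy$labels, cfg)
  p1 <- predict(m1, hold$table); p2 <- predict(m2, hold$table)
  expect_identical(p1$scores, p2$scores)
  expect_true(all(abs(p1$scores) <= 1))
  m3 <- blsvm(toy$table, toy$labels,
              blsvm_config(n_layers = 3, nodes_per_layer = 4, seed = 78))
  expect_false(identical(predict(m3, hold$table)$scores, p1$scores))
})

test_that("label negation mirrors the scores", {
  toy <- make_toy_cohort(n_pos = 20, n_neg = 20, seed = 26)
  cfg <- blsvm_config(n_layers = 2, nodes_per_layer = 4, seed = 3)
  s_pos <- predict(blsvm(toy$table, toy$labels, cfg), toy$table)$scores
  s_neg <- predict(blsvm(toy$table, -toy$labels, cfg), toy$table)$scores
  expect_gt(cor(s_pos, -s_neg), 0.95)
})

test_that("a well-separated cohort is fit perfectly on its training set", {
  cohort <- panel_cohort(seed = 51, effect_scale = 2)
  model <- blsvm(cohort$table, cohort$labels, blsvm_config(seed = 4))
  pred <- predict(model, cohort$table)
  expect_identical(pred$labels, cohort$labels)
})

test_that("missing cells are imputed from stored training medians", {
  cohort <- panel_cohort(seed = 52)
  model <- blsvm(cohort$table, cohort$labels,
                 blsvm_config(n_layers = 2, nodes_per_layer = 4, seed = 5))
  holed <- inject_missing(cohort$table, 0.1, seed = 6)
  pred <- predict(model, holed)
  expect_length(pred$scores, 39L)
  expect_true(all(is.finite(pred$scores)))
  # mild degradation only: most hard labels unchanged
  base <- predict(model, cohort$table)
  expect_gte(mean(pred$labels == base$labels), 0.85)
})

test_that("deep stacking does not catastrophically degrade held-out accuracy", {
  acc <- function(n_layers, s) {
    cohort <- panel_cohort(seed = 600 + s)
    folds <- stratified_folds(cohort$labels, 3, seed = s)
    tr <- folds != 1
    cfg <- blsvm_config(n_layers = n_layers, seed = s)
    model <- blsvm(cohort$table$values[tr, ], cohort$labels[tr], cfg)
    mean(predict(model, cohort$table$values[!tr, ])$labels ==
           cohort$labels[!tr])
  }
  deep <- mean(vapply(1:8, function(s) acc(5, s), 1))
  shallow <- mean(vapply(1:8, function(s) acc(1, s), 1))
  expect_gte(deep, shallow - 0.05)
})

test_that("degenerate inputs are hard errors", {
  toy <- make_toy_cohort(seed = 27)
  expect_error(blsvm(toy$table, rep(1L, 40), blsvm_config()), "class")
  expect_error(svm_node(toy$values, rep(1L, 40)), "both classes")
  v <- toy$values; v[1, 1] <- NA
  expect_error(svm_node(v, toy$labels), "complete")
})
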