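#' Configuration for the broad SVM ensemble
#'
#' The BL-SVM arranges `n_layers` x `nodes_per_layer` SVM nodes in a
#' shallow-but-broad scheme.  Layers are trained in order; every node in
#' layer `l` consumes the base features concatenated with the confidence
#' values (tanh of the decision value) of all `(l - 1) * m` nodes of the
#' previous layers, and each node trains on its own bootstrap resample of
#' the training set to diversify the ensemble.  There is no
#' backpropagation: each node is solved once, convexly.
#'
#' Defaults follow the published system where stated (5 layers) and
#' documented package choices where not: 8 nodes per layer, RBF kernel
#' with width `1/(input_dim * input_variance)`, cost `C = 1`.
#'
#' @param n_layers Number of layers `L` (>= 1, default 5).
#' @param nodes_per_layer Nodes `m` per layer (>= 1, default 8).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param cost Soft-margin cost `C` (> 0).
#' @param gamma Optional fixed RBF width; default derived per node.
#' @param class_weight Per-class penalty weighting of the soft margin
#'   (see [svm_node()]); `"balanced"` by default so the 23-vs-16 cohort
#'   imbalance does not shift the operating point.
#' @param bootstrap Resample the training set per node (default `TRUE`);
#'   single-class resamples are redrawn, at most 100 times.
#' @param imputation `"median"` (default) or `"mean"`: per-feature
#'   imputation learned from training data.
#' @param standardize Z-score base features using training statistics
#'   (default `TRUE`).
#' @param aggregation Final score: `"mean"` (default) of the last layer's
#'   confidences, or `"terminal_svm"`, an extra SVM trained on the fully
#'   augmented input whose confidence is the score.
#' @param seed Master seed; each node draws its bootstrap from a child
#'   seed keyed by (layer, node), so results are independent of training
#'   order.
#' @return Object of class `blsvm_config`.
#' @export
blsvm_config <- function(n_layers = 5L, nodes_per_layer = 8L,
                         kernel = c("rbf", "linear"), cost = 1,
                         gamma = NULL, class_weight = c("balanced", "none"),
                         bootstrap = TRUE,
                         imputation = c("median", "mean"),
                         standardize = TRUE,
                         aggregation = c("mean", "terminal_svm"),
                         seed = 1L) {
  kernel <- match.arg(kernel)
  class_weight <- match.arg(class_weight)
  imputation <- match.arg(imputation)
  aggregation <- match.arg(aggregation)
  stopifnot(n_layers >= 1L, nodes_per_layer >= 1L, cost > 0)
  structure(list(n_layers = as.integer(n_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 kernel = kernel, cost = cost, gamma = gamma,
                 class_weight = class_weight,
                 bootstrap = isTRUE(bootstrap), imputation = imputation,
                 standardize = isTRUE(standardize),
                 aggregation = aggregation, seed = as.integer(seed)),
            class = "blsvm_config")
}

#' Concatenate base input with accumulated confidences
#'
#' The input of a node in layer `l + 1` is the base feature vector
#' followed by the confidence values of all nodes of layers `1..l`,
#' layer-major, node index within layer: dimension `d + l * m`.
#'
#' @param x0 Base input (vector, or matrix with subjects in rows).
#' @param confidences List with one element per completed layer, each a
#'   length-`m` vector (or `n x m` matrix) of confidence values.
#' @return Vector (or matrix) of dimension `d + l * m`.
#' @export
augment_input <- function(x0, confidences = list()) {
  if (is.null(dim(x0))) x0 <- matrix(x0, nrow = 1L)
  if (length(confidences) == 0L) return(x0)
  mats <- lapply(confidences, function(ci) {
    if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1L)
    if (nrow(ci) != nrow(x0))
      stop("confidence block rows do not match the base input")
    ci
  })
  m <- ncol(mats[[1L]])
  if (any(vapply(mats, ncol, 1L) != m))
    stop("ragged confidence lists: every layer must contribute the same ",
         "number of nodes")
  do.call(cbind, c(list(x0), mats))
}

# learn imputation values + z-score parameters from training rows
fit_preprocess <- function(X, imputation, standardize) {
  fun <- if (imputation == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  impute_values <- apply(X, 2, fun)
  if (anyNA(impute_values))
    stop("feature(s) entirely missing in the training data: ",
         paste(colnames(X)[is.na(impute_values)], collapse = ", "))
  Xi <- X
  for (j in seq_len(ncol(Xi))) {
    miss <- is.na(Xi[, j])
    if (any(miss)) Xi[miss, j] <- impute_values[j]
  }
  zp <- if (standardize) zscore_params(Xi)
        else list(center = rep(0, ncol(Xi)), scale = rep(1, ncol(Xi)))
  list(impute_values = impute_values, center = zp$center, scale = zp$scale,
       Z = zscore_apply(Xi, zp))
}

apply_preprocess <- function(model, X) {
  if (!identical(colnames(X), model$feature_names))
    stop("table features do not match the model schema (expected ",
         length(model$feature_names), " features in training order)")
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- model$impute_values[j]
  }
  zscore_apply(X, list(center = model$center, scale = model$scale))
}

# bootstrap resample indices that contain both classes (bounded retries)
bootstrap_index <- function(y, max_tries = 100L) {
  n <- length(y)
  for (t in seq_len(max_tries)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) == 2L) return(idx)
  }
  stop("bootstrap resampling produced a single-class draw ", max_tries,
       " times in a row")
}

#' Fit a broad SVM ensemble
#'
#' Learns the preprocessing (imputation, then z-scoring) from the training
#' data, then trains the layers in order.  Node `(l, i)` trains on a
#' seeded bootstrap resample (size `K`, with replacement) of the training
#' set augmented with all previous layers' confidences; its input
#' dimension is therefore `d + (l - 1) * m`.  Everything is a pure
#' function of the data and the config seed.
#'
#' @param table A [feature_table] (missing values allowed; they are
#'   imputed) or a bare named matrix.
#' @param labels +1/-1 labels, at least 2 subjects per class.
#' @param config A [blsvm_config()].
#' @return Object of class `blsvm`: layers of [svm_node()]s plus the
#'   stored preprocessing state and config.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 3))
#' model <- blsvm(cohort$table, cohort$labels,
#'                blsvm_config(n_layers = 2, nodes_per_layer = 3, seed = 3))
#' pred <- predict(model, cohort$table)
#' mean(pred$labels == cohort$labels)
#' @export
blsvm <- function(table, labels, config = blsvm_config()) {
  stopifnot(inherits(config, "blsvm_config"))
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (is.null(colnames(X))) stop("training matrix needs column names")
  y <- check_labels(labels, nrow(X))
  if (sum(y == 1L) < 2L || sum(y == -1L) < 2L)
    stop("need at least 2 subjects per class")
  pre <- fit_preprocess(X, config$imputation, config$standardize)
  model <- structure(list(feature_names = colnames(X),
                          impute_values = pre$impute_values,
                          center = pre$center, scale = pre$scale,
                          layers = vector("list", config$n_layers),
                          terminal = NULL, config = config),
                     class = "blsvm")
  A <- pre$Z
  m <- config$nodes_per_layer
  for (l in seq_len(config$n_layers)) {
    conf_block <- matrix(NA_real_, nrow(A), m)
    nodes <- vector("list", m)
    for (i in seq_len(m)) {
      idx <- if (config$bootstrap) {
        with_seed(child_seed(config$seed, l, i), bootstrap_index(y))
      } else seq_along(y)
      node <- tryCatch(
        svm_node(A[idx, , drop = FALSE], y[idx], kernel = config$kernel,
                 cost = config$cost, gamma = config$gamma,
                 class_weight = config$class_weight),
        error = function(e) stop("node (", l, ", ", i, "): ",
                                 conditionMessage(e)))
      node$train_index <- idx
      nodes[[i]] <- node
      conf_block[, i] <- node_confidence(node, A)
    }
    model$layers[[l]] <- nodes
    A <- cbind(A, conf_block)
  }
  if (config$aggregation == "terminal_svm") {
    # aggregator sees the base input plus every layer's confidences
    model$terminal <- svm_node(A, y, kernel = config$kernel,
                               cost = config$cost, gamma = config$gamma,
                               class_weight = config$class_weight)
  }
  model
}

#' @export
print.blsvm <- function(x, ...) {
  cfg <- x$config
  cat("blsvm:", cfg$n_layers, "layers x", cfg$nodes_per_layer,
      "nodes (", cfg$kernel, "kernel, C =", cfg$cost, "),",
      length(x$feature_names), "base features\n")
  invisible(x)
}

#' Predict with a broad SVM ensemble
#'
#' Applies the stored imputation and z-scoring, propagates confidences
#' layer by layer, and scores each subject by the mean confidence of the
#' final layer (or the terminal aggregator's confidence).  Scores lie in
#' `[-1, 1]`; the hard label is `+1` when the score is strictly positive,
#' `-1` otherwise (a score of exactly 0 maps to `-1`).
#'
#' @param object A fitted [blsvm()].
#' @param table A [feature_table] or matrix with the model's features in
#'   training order; missing values allowed.
#' @param ... Unused.
#' @return List with `scores` (numeric in `[-1, 1]`) and `labels`
#'   (+1/-1 integers).
#' @export
predict.blsvm <- function(object, table, ...) {
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  A <- apply_preprocess(object, X)
  last_conf <- NULL
  for (nodes in object$layers) {
    conf_block <- vapply(nodes, function(nd) node_confidence(nd, A),
                         numeric(nrow(A)))
    conf_block <- matrix(conf_block, nrow = nrow(A))
    last_conf <- conf_block
    A <- cbind(A, conf_block)
  }
  scores <- if (!is.null(object$terminal)) {
    node_confidence(object$terminal, A)
  } else {
    rowMeans(last_conf)
  }
  labels <- ifelse(scores > 0, 1L, -1L)
  list(scores = as.numeric(scores), labels = as.integer(labels))
}

#' Input dimension of every node of a fitted ensemble
#'
#' Returns the `L x m` matrix of node input dimensions; by construction
#' entry `(l, i)` equals `d + (l - 1) * m`.
#'
#' @param model A fitted [blsvm()].
#' @return Integer matrix, layers in rows.
#' @export
node_input_dims <- function(model) {
  stopifnot(inherits(model, "blsvm"))
  t(vapply(model$layers,
           function(nodes) vapply(nodes, function(nd) nd$input_dim, 1L),
           integer(model$config$nodes_per_layer)))
}
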