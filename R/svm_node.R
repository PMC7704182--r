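#' Train a single soft-margin SVM node
#'
#' One max-margin separator, the unit the broad ensemble is built from.
#' The published formulation is the hard-margin program (maximise the
#' margin `2/||w||` subject to `y_k (w'x_k + b) >= 1`); here the standard
#' soft-margin relaxation with cost `C` is solved (libsvm via
#' \pkg{e1071}), since 39 noisy subjects are not separable in general and
#' the hard margin is recovered as `C -> Inf`.  Inputs must be complete
#' and are used unscaled -- callers own imputation and standardisation.
#'
#' @param X Numeric matrix (no `NA`), rows = samples.
#' @param y +1/-1 labels, both classes present.
#' @param kernel `"rbf"` or `"linear"`.
#' @param cost Soft-margin cost `C` (> 0).
#' @param gamma RBF width; default `1 / (ncol(X) * var(X))` (the variance
#'   taken over all entries), i.e. scales with the input dimension.
#' @param class_weight `"balanced"` (default) scales each class's
#'   margin-violation penalty by `n / (2 * n_class)`, so the relaxation
#'   penalises both classes symmetrically as the hard-margin program does
#'   regardless of the 23-vs-16 cohort imbalance; `"none"` uses the plain
#'   unweighted penalty.
#' @return Object of class `svm_node`: the fitted \pkg{e1071} model plus
#'   `input_dim`, `kernel`, `cost`, `gamma` and a sign `flip` making
#'   positive decision values point at class +1.
#' @export
svm_node <- function(X, y, kernel = c("rbf", "linear"), cost = 1,
                     gamma = NULL, class_weight = c("balanced", "none")) {
  class_weight <- match.arg(class_weight)
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (anyNA(X)) stop("svm_node requires complete inputs (impute first)")
  if (!all(is.finite(X))) stop("svm_node requires finite inputs")
  y <- check_labels(y, nrow(X))
  if (length(unique(y)) < 2L) stop("svm_node needs both classes present")
  if (cost <= 0) stop("cost must be positive")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- 1 / (ncol(X) * if (is.finite(v) && v > 0) v else 1)
  }
  yf <- factor(y, levels = c(-1L, 1L))
  cw <- if (class_weight == "balanced") {
    n <- length(y)
    c("-1" = n / (2 * sum(y == -1L)), "1" = n / (2 * sum(y == 1L)))
  } else NULL
  fit <- e1071::svm(X, yf, type = "C-classification",
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    cost = cost, gamma = gamma, scale = FALSE,
                    class.weights = cw)
  # libsvm orients decision values toward the first training label it sees;
  # record a flip so that positive always means class +1
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (identical(colnames(dv), "-1/1")) -1 else 1
  structure(list(fit = fit, input_dim = ncol(X), kernel = kernel,
                 cost = cost, gamma = gamma, flip = flip,
                 train_index = attr(X, "train_index")),
            class = "svm_node")
}

#' Signed decision value of a node
#'
#' The (kernelised) distance-like decision value `w'x + b`; positive means
#' class +1 (NPSLE side).
#'
#' @param node An [svm_node()].
#' @param X Matrix of inputs, `ncol(X) == node$input_dim`.
#' @return Numeric vector of decision values.
#' @export
node_decision <- function(node, X) {
  X <- as.matrix(X)
  if (ncol(X) != node$input_dim)
    stop("input dimension ", ncol(X), " does not match node dimension ",
         node$input_dim)
  dv <- attr(stats::predict(node$fit, X, decision.values = TRUE),
             "decision.values")
  node$flip * as.numeric(dv)
}

#' Confidence value of a node
#'
#' `tanh` of the decision value: strictly inside (-1, 1), odd, sign equal
#' to the node's hard classification, magnitude growing with distance from
#' the separating surface.  These are the values that augment the input of
#' subsequent layers.
#'
#' @inheritParams node_decision
#' @return Numeric vector in (-1, 1).
#' @export
node_confidence <- function(node, X) {
  tanh(node_decision(node, X))
}

# |w| (or w^2) importances of a *linear* node, for recursive elimination
node_importance <- function(node, type = c("abs_weight", "squared_weight")) {
  type <- match.arg(type)
  if (node$kernel != "linear")
    stop("feature importances are defined for linear nodes only")
  w <- as.numeric(t(node$fit$coefs) %*% node$fit$SV)
  if (type == "abs_weight") abs(w) else w^2
}
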