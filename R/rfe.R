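#' Configuration for SVM recursive feature elimination
#'
#' @param importance Per-feature importance of the linear max-margin
#'   separator: `"abs_weight"` (default) or `"squared_weight"`.
#' @param step Features removed per iteration (>= 1).
#' @param cv_folds,cv_repeats Stratified cross-validation used to score
#'   each visited panel size (defaults 3 folds x 5 repeats).
#' @param cost Soft-margin cost of the linear separators.
#' @param seed Integer seed driving the fold draws.
#' @return Object of class `rfe_config`.
#' @export
rfe_config <- function(importance = c("abs_weight", "squared_weight"),
                       step = 1L, cv_folds = 3L, cv_repeats = 5L,
                       cost = 1, seed = 1L) {
  importance <- match.arg(importance)
  stopifnot(step >= 1L, cv_folds >= 2L, cv_repeats >= 1L, cost > 0)
  structure(list(importance = importance, step = as.integer(step),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats), cost = cost,
                 seed = as.integer(seed)),
            class = "rfe_config")
}

# z-scoring helpers shared by RFE and the ensemble: parameters learned on
# training rows only; zero-variance columns get sd 1 (so they z-score to a
# constant and a linear SVM gives them ~zero weight)
zscore_params <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
zscore_apply <- function(X, zp) {
  sweep(sweep(X, 2, zp$center, "-"), 2, zp$scale, "/")
}

# One elimination pass on (already standardised) training data.  At every
# visited size a linear SVM is fit on the surviving features; `score_fun`,
# if given, receives (surviving, fit) and its result is recorded.  Ties in
# importance are broken by column (schema) order: the earlier column goes.
rfe_path <- function(Z, y, step, importance, cost, score_fun = NULL) {
  surviving <- seq_len(ncol(Z))
  sizes <- integer(0); panels <- list(); scores <- numeric(0)
  eliminated <- integer(0)
  repeat {
    node <- svm_node(Z[, surviving, drop = FALSE], y, kernel = "linear",
                     cost = cost)
    sizes <- c(sizes, length(surviving))
    panels[[length(panels) + 1L]] <- surviving
    if (!is.null(score_fun))
      scores <- c(scores, score_fun(surviving, node))
    if (length(surviving) == 1L) break
    imp <- node_importance(node, importance)
    k <- min(step, length(surviving) - 1L)
    drop_local <- order(imp, seq_along(surviving))[seq_len(k)]
    eliminated <- c(eliminated, surviving[sort(drop_local)])
    surviving <- surviving[-drop_local]
  }
  list(sizes = sizes, panels = panels, scores = scores,
       elim_order = c(eliminated, surviving))
}

#' Recursive feature elimination with a cross-validated size curve
#'
#' Starting from the full feature set, repeatedly fits a linear
#' soft-margin SVM on standardised features, removes the `step` features
#' with the smallest importance (|weight| of the separator), and records
#' the panel at every visited size -- mirroring the published selection
#' procedure.  Each visited size is scored by repeated stratified
#' cross-validation in which the elimination is re-run inside every
#' training fold (so the score at a size never sees its own test fold),
#' and the returned panel is read off a final elimination pass on the full
#' data.  Requires complete data: impute missing values upstream.
#'
#' @param table A [feature_table] without missing values.
#' @param labels +1/-1 labels.
#' @param config An [rfe_config()].
#' @return Object of class `rfe_curve`: list with `points` (data frame
#'   `size`, `score_mean`, `score_sd` -- CV accuracy per visited size),
#'   `ranking` (named integer vector, 1 = most important = last
#'   eliminated), `elim_order` (feature names, first eliminated first),
#'   `panels` (full-data panel at each visited size) and `selected_panel`
#'   (features at the score-maximising size; ties go to the smaller
#'   panel).
#' @export
rfe_rank <- function(table, labels, config = rfe_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "rfe_config"))
  X <- table$values
  if (anyNA(X))
    stop("rfe_rank requires complete data; impute missing values first ",
         "(e.g. median imputation)")
  y <- check_labels(labels, nrow(X))
  if (!all(c(-1L, 1L) %in% y)) stop("both classes must be present")
  d <- ncol(X)

  # cross-validated score per size: elimination re-run per training fold
  n_sizes <- ceiling((d - 1) / config$step) + 1L
  score_mat <- matrix(NA_real_, n_sizes,
                      config$cv_repeats * config$cv_folds)
  col <- 0L
  for (r in seq_len(config$cv_repeats)) {
    folds <- stratified_folds(y, config$cv_folds,
                              seed = child_seed(config$seed, r))
    for (f in seq_len(config$cv_folds)) {
      col <- col + 1L
      tr <- folds != f; te <- folds == f
      zp <- zscore_params(X[tr, , drop = FALSE])
      Ztr <- zscore_apply(X[tr, , drop = FALSE], zp)
      Zte <- zscore_apply(X[te, , drop = FALSE], zp)
      yte <- y[te]
      path <- rfe_path(Ztr, y[tr], config$step, config$importance,
                       config$cost,
                       score_fun = function(surv, node) {
                         pred <- sign(node_decision(node,
                                                    Zte[, surv, drop = FALSE]))
                         pred[pred == 0] <- -1
                         mean(pred == yte)
                       })
      score_mat[, col] <- path$scores
    }
  }

  # final elimination pass on the full (standardised) data
  zp <- zscore_params(X)
  full <- rfe_path(zscore_apply(X, zp), y, config$step, config$importance,
                   config$cost)
  stopifnot(length(full$sizes) == n_sizes)

  points <- data.frame(size = full$sizes,
                       score_mean = rowMeans(score_mat),
                       score_sd = apply(score_mat, 1, stats::sd))
  ranking <- integer(d)
  ranking[full$elim_order] <- rev(seq_len(d))
  names(ranking) <- colnames(X)
  panels <- lapply(full$panels, function(idx) colnames(X)[idx])
  curve <- structure(list(points = points, ranking = ranking,
                          elim_order = colnames(X)[full$elim_order],
                          panels = panels, selected_panel = NULL),
                     class = "rfe_curve")
  curve$selected_panel <- select_panel(curve)
  curve
}

#' Read a panel off an RFE curve
#'
#' Returns the feature panel at the size maximising the mean CV score
#' (ties broken toward the smaller panel), or at an explicitly requested
#' size -- the published pipeline fixed its panel at 26 features.
#'
#' @param curve An `rfe_curve` from [rfe_rank()].
#' @param size Optional panel size override; must be a visited size.
#' @return Character vector of feature names.
#' @export
select_panel <- function(curve, size = NULL) {
  stopifnot(inherits(curve, "rfe_curve"), nrow(curve$points) >= 1L)
  sizes <- curve$points$size
  if (!is.null(size)) {
    i <- match(size, sizes)
    if (is.na(i)) stop("size ", size, " was not visited by the elimination")
  } else {
    best <- max(curve$points$score_mean)
    cand <- which(curve$points$score_mean == best)
    i <- cand[which.min(sizes[cand])]
  }
  curve$panels[[i]]
}

#' @export
print.rfe_curve <- function(x, ...) {
  cat("rfe_curve over", nrow(x$points), "panel sizes; best mean CV score",
      format(max(x$points$score_mean), digits = 3), "at size",
      length(x$selected_panel), "\n")
  invisible(x)
}
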