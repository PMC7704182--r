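#' Configuration for repeated cross-validated evaluation
#'
#' @param folds Folds `k` per repeat (default 3, as published).
#' @param repeats Repeats `R` with fresh fold draws (published analysis:
#'   50).
#' @param threshold Score threshold for hard labels (default 0).
#' @param stratify Preserve class proportions per fold (default `TRUE`;
#'   `FALSE` restores plain random splitting).
#' @param nested_selection Re-run RFE inside every training fold and
#'   classify on the fold-selected panel (default `FALSE`: evaluate the
#'   panel the table already carries).
#' @param rfe An [rfe_config()] used when `nested_selection = TRUE`.
#' @param seed Master seed; repeat `r` derives its folds and model seeds
#'   from it.
#' @return Object of class `eval_config`.
#' @export
eval_config <- function(folds = 3L, repeats = 50L, threshold = 0,
                        stratify = TRUE, nested_selection = FALSE,
                        rfe = rfe_config(), seed = 1L) {
  stopifnot(folds >= 2L, repeats >= 1L)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 threshold = threshold, stratify = isTRUE(stratify),
                 nested_selection = isTRUE(nested_selection), rfe = rfe,
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Stratified fold assignment
#'
#' Shuffles each class with the seeded RNG and deals members so that fold
#' sizes differ by at most one both per class and overall (class
#' remainders are routed to the currently smallest folds).  With
#' `stratify = FALSE` subjects are dealt irrespective of class (overall
#' sizes still differ by at most one).
#'
#' @param labels +1/-1 labels.
#' @param k Number of folds; every class must have at least `k` members
#'   when stratifying (`n >= k` otherwise).
#' @param seed Integer seed.
#' @param stratify Preserve class proportions (default `TRUE`).
#' @return Integer vector of fold ids in `1..k`, one per subject.
#' @export
stratified_folds <- function(labels, k, seed = 1L, stratify = TRUE) {
  labels <- as_cohort_labels(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds")
  with_seed(seed, {
    fold <- integer(n)
    if (!stratify) {
      if (n < k) stop("fewer subjects than folds")
      return(sample(rep(seq_len(k), length.out = n)))
    }
    totals <- rep(0L, k)
    for (cls in c(1L, -1L)) {
      members <- which(labels == cls)
      n_c <- length(members)
      if (n_c < k)
        stop("class ", cls, " has ", n_c, " members but ", k,
             " folds were requested")
      members <- members[sample.int(n_c)]
      base <- n_c %/% k
      extra <- n_c %% k
      sizes <- rep(base, k)
      if (extra > 0L) {
        # remainders go to the folds currently smallest overall;
        # ties are broken randomly so assignments vary with the seed
        recv <- order(totals, stats::runif(k))[seq_len(extra)]
        sizes[recv] <- sizes[recv] + 1L
      }
      fold[members] <- rep(seq_len(k), times = sizes)
      totals <- totals + sizes
    }
    fold
  })
}

#' ROC curve and AUC from continuous scores
#'
#' AUC by the rank (Mann-Whitney) formulation with half credit for tied
#' scores; ROC points enumerate every distinct threshold.
#'
#' @param scores Finite per-subject scores (larger = more NPSLE-like).
#' @param labels +1/-1 labels, both classes present.
#' @return List of class `roc_result`: `auc` and `roc`, a data frame of
#'   `threshold`, `fpr`, `tpr` (including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_cohort_labels(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (!all(c(-1L, 1L) %in% labels)) stop("both classes must be present")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == -1L)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), 1)
  fpr <- vapply(thr, function(t) mean(scores[labels == -1L] >= t), 1)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(auc = auc, roc = roc), class = "roc_result")
}

#' Sensitivity, specificity and accuracy of hard labels
#'
#' Sensitivity is the true-positive rate among NPSLE subjects (+1),
#' specificity the true-negative rate among controls (-1).
#'
#' @param pred_labels,true_labels Vectors in `{-1, +1}`, same length.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
sens_spec <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop("prediction and truth differ in length")
  ok <- function(v) all(v %in% c(-1, 1))
  if (!ok(pred_labels) || !ok(true_labels))
    stop("labels must be coded -1/+1")
  tp <- sum(pred_labels == 1 & true_labels == 1)
  fn <- sum(pred_labels == -1 & true_labels == 1)
  tn <- sum(pred_labels == -1 & true_labels == -1)
  fp <- sum(pred_labels == 1 & true_labels == -1)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(true_labels))
}

#' Repeated stratified cross-validated evaluation of the BL-SVM
#'
#' For every repeat `r`, draws fresh (stratified) folds, trains the
#' ensemble on `k - 1` folds and scores the held-out fold, then pools the
#' held-out scores of the repeat into one ROC AUC and one confusion
#' matrix at the score threshold.  With `nested_selection = TRUE` the RFE
#' panel is re-selected inside every training fold, so feature selection
#' never sees its test subjects.  Fully reproducible from the master
#' seed.
#'
#' @param table A [feature_table].
#' @param labels +1/-1 labels.
#' @param blsvm_config A [blsvm_config()]; its seed is replaced by
#'   per-(repeat, fold) child seeds.
#' @param config An [eval_config()].
#' @return Object of class `cv_report`: `per_repeat` (data frame with one
#'   row per repeat: `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   plus the Youden-optimal threshold as a secondary statistic),
#'   `summary` (mean/median/quartiles/min/max per metric),
#'   `fold_assignments` (`n x R` matrix), `scores` (`n x R` pooled
#'   held-out scores) and the two configs.
#' @export
repeated_cv <- function(table, labels, blsvm_config = blsvm_config(),
                        config = eval_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(blsvm_config, "blsvm_config"),
            inherits(config, "eval_config"))
  X <- table$values
  y <- check_labels(labels, nrow(X))
  n <- length(y)
  per_repeat <- vector("list", config$repeats)
  fold_assignments <- matrix(NA_integer_, n, config$repeats)
  score_mat <- matrix(NA_real_, n, config$repeats,
                      dimnames = list(rownames(X), NULL))
  for (r in seq_len(config$repeats)) {
    rseed <- child_seed(config$seed, r)
    folds <- stratified_folds(y, config$folds, seed = rseed,
                              stratify = config$stratify)
    fold_assignments[, r] <- folds
    scores <- rep(NA_real_, n)
    for (f in seq_len(config$folds)) {
      tr <- folds != f; te <- folds == f
      cols <- colnames(X)
      if (config$nested_selection) {
        rc <- config$rfe
        rc$seed <- child_seed(rseed, f, 1L)
        tr_tab <- feature_table(X[tr, , drop = FALSE])
        if (anyNA(tr_tab$values)) {
          med <- apply(tr_tab$values, 2, stats::median, na.rm = TRUE)
          vv <- tr_tab$values
          for (j in seq_len(ncol(vv))) vv[is.na(vv[, j]), j] <- med[j]
          tr_tab <- feature_table(vv)
        }
        cols <- rfe_rank(tr_tab, y[tr], rc)$selected_panel
      }
      cfg <- blsvm_config
      cfg$seed <- child_seed(rseed, f, 2L)
      model <- tryCatch(
        blsvm(X[tr, cols, drop = FALSE], y[tr], cfg),
        error = function(e) stop("repeat ", r, " (seed ", rseed,
                                 "), fold ", f, ": ", conditionMessage(e)))
      scores[te] <- predict(model, X[te, cols, drop = FALSE])$scores
    }
    stopifnot(!anyNA(scores))
    score_mat[, r] <- scores
    pred <- ifelse(scores > config$threshold, 1L, -1L)
    ss <- sens_spec(pred, y)
    roc <- roc_auc(scores, y)
    youden <- with(roc$roc, threshold[which.max(tpr - fpr)])
    per_repeat[[r]] <- data.frame(
      repeat_id = r, auc = roc$auc, sensitivity = ss[["sensitivity"]],
      specificity = ss[["specificity"]], accuracy = ss[["accuracy"]],
      youden_threshold = youden)
  }
  per_repeat <- do.call(rbind, per_repeat)
  metrics <- c("auc", "sensitivity", "specificity", "accuracy")
  summary <- t(vapply(metrics, function(mm) {
    v <- per_repeat[[mm]]
    c(mean = mean(v), median = stats::median(v),
      q1 = unname(stats::quantile(v, 0.25)),
      q3 = unname(stats::quantile(v, 0.75)),
      min = min(v), max = max(v))
  }, numeric(6)))
  structure(list(per_repeat = per_repeat, summary = summary,
                 fold_assignments = fold_assignments, scores = score_mat,
                 blsvm_config = blsvm_config, eval_config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report: ", nrow(x$per_repeat), " repeats of ",
      x$eval_config$folds, "-fold cross-validation\n", sep = "")
  print(round(x$summary, 4))
  invisible(x)
}
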