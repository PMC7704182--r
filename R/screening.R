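#' Mann-Whitney U test for one feature
#'
#' Two-sided rank-sum comparison of NPSLE values `x` against control
#' values `y`.  `U` counts the pairs where an `x` value exceeds a `y`
#' value, ties credited 1/2 (so `0 <= U <= n_pos * n_neg`).  The p-value
#' comes from [stats::wilcox.test()]: by default the normal approximation
#' with tie and continuity corrections; `exact = TRUE` requests exact
#' enumeration (valid without ties, practical for small samples).
#' Missing values are dropped per group.
#'
#' @param x Values for the positive (NPSLE) group.
#' @param y Values for the negative (control) group.
#' @param exact Use the exact null distribution instead of the normal
#'   approximation.
#' @return List of class `mw_utest`: `u`, `p_value`, `n_pos`, `n_neg`,
#'   `tie_correction_applied`.
#' @export
mw_utest <- function(x, y, exact = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 non-missing values per group (got ",
         length(x), " and ", length(y), ")")
  ties <- anyDuplicated(c(x, y)) > 0L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact && !ties, correct = TRUE))
  structure(list(u = unname(wt$statistic), p_value = wt$p.value,
                 n_pos = length(x), n_neg = length(y),
                 tie_correction_applied = ties && !exact),
            class = "mw_utest")
}

#' Directional per-feature ROC AUC
#'
#' `AUC = U / (n_pos * n_neg)`: the probability that a random NPSLE value
#' exceeds a random control value, plus half the tie probability.
#' Directional: values below 0.5 (feature lower in patients) are returned
#' as-is, not folded.
#'
#' @inheritParams mw_utest
#' @return A single number in `[0, 1]`.
#' @export
feature_auc <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 non-missing values per group")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

#' Univariate screening of every feature
#'
#' Applies [mw_utest()] and [feature_auc()] per feature (missing values
#' dropped per feature per group) and flags the significant set at level
#' `alpha` on the raw p-values -- matching the published analysis, which
#' applies no multiplicity correction.  Benjamini-Hochberg adjusted
#' p-values are available behind `adjust = "BH"`.
#'
#' @param table A [feature_table].
#' @param labels +1/-1 labels (or anything [as_cohort_labels()] accepts).
#' @param alpha Significance level on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param exact Passed to [mw_utest()].
#' @return Object of class `screening_report`: a data frame with one row
#'   per feature (`feature`, `u`, `p_value`, `p_adjusted` if requested,
#'   `auc`, `n_pos`, `n_neg`, `n_missing_pos`, `n_missing_neg`,
#'   `significant`), with `alpha` and the significant feature set as
#'   attributes.
#' @export
screen_features <- function(table, labels, alpha = 0.05,
                            adjust = c("none", "BH"), exact = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  adjust <- match.arg(adjust)
  labels <- check_labels(labels, nrow(table$values))
  if (!all(c(-1L, 1L) %in% labels)) stop("both classes must be present")
  values <- table$values
  rows <- lapply(colnames(values), function(j) {
    x <- values[labels == 1L, j]
    y <- values[labels == -1L, j]
    if (all(is.na(x)) || all(is.na(y)))
      stop("feature '", j, "' is entirely missing in one group")
    ut <- mw_utest(x, y, exact = exact)
    data.frame(feature = j, u = ut$u, p_value = ut$p_value,
               auc = feature_auc(x, y),
               n_pos = ut$n_pos, n_neg = ut$n_neg,
               n_missing_pos = sum(is.na(x)), n_missing_neg = sum(is.na(y)),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  if (adjust == "BH") {
    rep$p_adjusted <- stats::p.adjust(rep$p_value, method = "BH")
    rep$significant <- rep$p_adjusted < alpha
  } else {
    rep$significant <- rep$p_value < alpha
  }
  attr(rep, "alpha") <- alpha
  attr(rep, "significant_features") <- rep$feature[rep$significant]
  class(rep) <- c("screening_report", "data.frame")
  rep
}
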