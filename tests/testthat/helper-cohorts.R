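# Small programmatic fixtures shared across the test files.

# Two-class Gaussian toy cohort: `d_inf` informative features (group means
# +/- gap/2, unit-free sd) followed by `d_noise` pure-noise features.
make_toy_cohort <- function(n_pos = 20, n_neg = 20, d_inf = 1, d_noise = 9,
                            gap = 4, sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  d <- d_inf + d_noise
  X <- matrix(rnorm(n * d), n, d)
  y <- c(rep(1L, n_pos), rep(-1L, n_neg))
  for (j in seq_len(d_inf))
    X[, j] <- X[, j] * sd + ifelse(y == 1L, gap / 2, -gap / 2)
  colnames(X) <- sprintf("f%02d", seq_len(d))
  list(table = feature_table(X), labels = y, values = X)
}

# Brute-force Mann-Whitney U: count x-over-y pairs, ties worth 1/2.
brute_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Brute-force AUC over all between-class score pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  brute_u(pos, neg) / (length(pos) * length(neg))
}

# Default-size reference cohort restricted to the published 26-feature panel.
panel_cohort <- function(seed, ...) {
  cohort <- generate_cohort(cohort_config(seed = seed, ...))
  panel <- reference_panel()
  list(table = feature_table(cohort$table$values[, panel, drop = FALSE],
                             subject_ids = rownames(cohort$table$values)),
       labels = cohort$labels)
}
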