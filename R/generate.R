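#' Configuration for the synthetic cohort generator
#'
#' The generator draws class-conditional Gaussian cohorts from a
#' `group_params` table, emulating the study design whose raw data are
#' withheld: 23 NPSLE patients, 16 healthy controls, 117 independent
#' features with the published per-group means and dispersions.
#'
#' `dispersion_mode` fixes the reading of the published "+/-" values: mode
#' `"sd"` uses them directly as the sampling standard deviation; mode
#' `"sem"` (the default) treats them as standard errors and reconstructs
#' the SD as `dispersion * sqrt(n_group)` with the *reference* group sizes
#' (23/16), since that is the n the printed errors were computed from.
#'
#' `effect_scale` moves each feature's two group means toward (`< 1`) or
#' away from (`> 1`) their midpoint; `0` gives an exchangeable null world,
#' `1` reproduces the published separations.
#'
#' @param params A `group_params` table ([reference_params()] by default).
#' @param n_pos,n_neg Simulated group sizes (defaults 23 NPSLE / 16 HC).
#' @param dispersion_mode `"sem"` or `"sd"`.
#' @param missing_rate Cell-wise missing-completely-at-random rate in
#'   `[0, 1)` applied after sampling (default 0).
#' @param effect_scale Nonnegative multiplier on group-mean separation.
#' @param clip_at_zero If `TRUE`, negative draws are clipped to 0
#'   (concentrations are physical quantities; off by default).
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(params = reference_params(), n_pos = 23L,
                          n_neg = 16L, dispersion_mode = c("sem", "sd"),
                          missing_rate = 0, effect_scale = 1,
                          clip_at_zero = FALSE, seed = 1L) {
  dispersion_mode <- match.arg(dispersion_mode)
  stopifnot(n_pos >= 2L, n_neg >= 2L, effect_scale >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(params = params, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), dispersion_mode = dispersion_mode,
                 missing_rate = missing_rate, effect_scale = effect_scale,
                 clip_at_zero = clip_at_zero, seed = as.integer(seed)),
            class = "cohort_config")
}

# per-feature sampling moments implied by a config (exposed for test oracles)
cohort_moments <- function(config) {
  p <- config$params
  n_ref_pos <- attr(p, "n_pos") %||% 23L
  n_ref_neg <- attr(p, "n_neg") %||% 16L
  mult_pos <- if (config$dispersion_mode == "sem") sqrt(n_ref_pos) else 1
  mult_neg <- if (config$dispersion_mode == "sem") sqrt(n_ref_neg) else 1
  mid <- (p$npsle_mean + p$hc_mean) / 2
  data.frame(
    feature = p$feature,
    mean_pos = mid + config$effect_scale * (p$npsle_mean - mid),
    mean_neg = mid + config$effect_scale * (p$hc_mean - mid),
    sd_pos = p$npsle_disp * mult_pos,
    sd_neg = p$hc_disp * mult_neg,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic class-conditional cohort
#'
#' Each feature is drawn independently per subject from a Gaussian with
#' the feature's (effect-scaled) group mean and the SD implied by
#' `dispersion_mode` (see [cohort_config()]).  Rows are laid out positives
#' first, then shuffled with the seeded RNG; if `missing_rate > 0`,
#' [inject_missing()] is applied with a derived seed.  The result is a
#' pure function of the config, bit-identical across calls.
#'
#' @param config A [cohort_config()].
#' @return List with `table` (a [feature_table], `n_pos + n_neg` subjects x
#'   117 features) and `labels` (+1/-1 integer vector).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' dim(cohort$table)      # 39 117
#' sum(cohort$labels == 1)  # 23
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  mom <- cohort_moments(config)
  n_pos <- config$n_pos
  n_neg <- config$n_neg
  n <- n_pos + n_neg
  d <- nrow(mom)
  out <- with_seed(config$seed, {
    values <- matrix(NA_real_, n, d, dimnames = list(NULL, mom$feature))
    for (j in seq_len(d)) {
      values[, j] <- c(stats::rnorm(n_pos, mom$mean_pos[j], mom$sd_pos[j]),
                       stats::rnorm(n_neg, mom$mean_neg[j], mom$sd_neg[j]))
    }
    if (config$clip_at_zero) values[values < 0] <- 0
    ord <- sample.int(n)
    list(values = values[ord, , drop = FALSE],
         labels = c(rep(1L, n_pos), rep(-1L, n_neg))[ord])
  })
  table <- feature_table(out$values,
                         subject_ids = sprintf("S%03d", seq_len(n)),
                         check_schema = FALSE)
  if (config$missing_rate > 0)
    table <- inject_missing(table, config$missing_rate,
                            seed = child_seed(config$seed, 1e6))
  list(table = table, labels = out$labels)
}

#' Mask cells missing-completely-at-random
#'
#' Each cell is masked independently with probability `missing_rate`
#' (MCAR), emulating the dropouts that spectral quality control produces
#' in real concentration tables.  A row that would lose all its features
#' has its mask redrawn, so no subject ever comes out fully missing.  The
#' pre-mask values are retained in the `"shadow"` attribute for test
#' oracles; consumers of the table only see `NA`.
#'
#' @param table A [feature_table].
#' @param missing_rate Probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A new [feature_table] with `NA` in masked cells.
#' @export
inject_missing <- function(table, missing_rate, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (missing_rate == 0) return(table)
  values <- table$values
  n <- nrow(values); d <- ncol(values)
  mask <- with_seed(seed, {
    m <- matrix(stats::runif(n * d) < missing_rate, n, d)
    for (i in seq_len(n)) {
      while (all(m[i, ])) m[i, ] <- stats::runif(d) < missing_rate
    }
    m
  })
  masked <- values
  masked[mask] <- NA_real_
  out <- feature_table(masked, subject_ids = rownames(values))
  attr(out, "shadow") <- values
  out
}
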