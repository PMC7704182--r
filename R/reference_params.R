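#' Published NPSLE-vs-control group statistics
#'
#' Loads the packaged transcription of the published per-feature group
#' statistics for the study cohort (23 NPSLE patients, 16 healthy
#' controls): per-region, per-metabolite group mean and dispersion, the
#' printed two-sided Mann-Whitney p-value, the printed single-feature ROC
#' AUC, the printed asterisk markers, and two derived masks --
#' `significant` (the 33 features with printed p < 0.05) and `selected`
#' (the published 26-feature classifier panel).  Transcription corrections
#' are documented in the provenance sidecar shipped next to the CSV
#' (`npsle_mrs_reference_PROVENANCE.txt`); the file's md5 checksum is
#' verified at load.
#'
#' The source never states whether the printed dispersions are standard
#' deviations or standard errors; both readings are supported downstream
#' via `dispersion_mode` (see [cohort_config()]).
#'
#' @return A data frame of class `group_params` with one row per feature
#'   (117) and columns `feature`, `region`, `metabolite`, `hc_mean`,
#'   `hc_disp`, `npsle_mean`, `npsle_disp`, `p_value`, `auc`, `marker`,
#'   `significant`, `selected`; attributes `n_pos` (23), `n_neg` (16).
#' @examples
#' p <- reference_params()
#' sum(p$significant)  # 33
#' sum(p$selected)     # 26
#' @export
reference_params <- function() {
  path <- system.file("extdata", "npsle_mrs_reference.csv", package = "blsvm")
  if (path == "") stop("packaged reference table not found")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, "5bf3aba5c658ccceabcc4768b9646325"))
    stop("reference table checksum mismatch (got ", md5,
         "); the packaged fixture has been altered")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 117L, !anyDuplicated(df$feature),
            all(df$hc_disp > 0), all(df$npsle_disp > 0),
            all(df$feature %in% mrs_schema()$feature_names))
  attr(df, "n_pos") <- 23L
  attr(df, "n_neg") <- 16L
  class(df) <- c("group_params", "data.frame")
  df
}

#' Published feature masks
#'
#' Convenience accessors for the two feature sets the published analysis
#' reports: the 33 features with a significant univariate group difference
#' (printed p < 0.05) and the 26-feature panel retained by recursive
#' feature elimination for the classifier.
#'
#' @param params A `group_params` table, by default [reference_params()].
#' @return Character vector of feature names.
#' @export
reference_panel <- function(params = reference_params()) {
  params$feature[params$selected == 1L]
}

#' @rdname reference_panel
#' @export
reference_significant <- function(params = reference_params()) {
  params$feature[params$significant == 1L]
}
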