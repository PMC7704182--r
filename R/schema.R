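#' The multivoxel MRS feature schema
#'
#' The study design samples 9 brain regions on the basal-ganglion slab
#' (bilateral posterior cingulate gyrus, dorsal thalamus, lentiform nucleus
#' and paratrigonal white matter, plus the right insula) and quantifies 13
#' metabolite measures per region: absolute concentrations, sums of
#' overlapping resonances, and ratios against total creatine.  The cross
#' product gives the 117 named features every table in this package is
#' keyed by.  Feature names use the `REGION.MEASURE` form with `.` as the
#' separator, because measure names themselves contain `+` and `/`.
#'
#' @return An object of class `mrs_schema`: a list with `regions` (9 region
#'   codes), `metabolites` (13 measure codes) and `feature_names` (their
#'   cross product, region-major, length 117).
#' @examples
#' s <- mrs_schema()
#' length(s$feature_names)  # 117
#' @export
mrs_schema <- function() {
  regions <- c("RPCG", "LPCG", "RDT", "LDT", "RLN", "LLN", "RI",
               "RPWM", "LPWM")
  metabolites <- c("Cr", "PCr", "Cr+PCr", "NAA", "NAAG", "NAA+NAAG",
                   "NAA+NAAG/Cr+PCr", "mI", "mI/Cr+PCr", "Cho+PCh",
                   "Cho+PCh/Cr+PCr", "Glu+Gln", "Glu+Gln/Cr+PCr")
  feature_names <- as.vector(t(outer(regions, metabolites, paste, sep = ".")))
  structure(list(regions = regions, metabolites = metabolites,
                 feature_names = feature_names),
            class = "mrs_schema")
}

#' @export
print.mrs_schema <- function(x, ...) {
  cat("Multivoxel MRS feature schema:", length(x$regions), "regions x",
      length(x$metabolites), "measures =", length(x$feature_names),
      "features\n")
  cat("  regions:    ", paste(x$regions, collapse = ", "), "\n")
  cat("  metabolites:", paste(x$metabolites, collapse = ", "), "\n")
  invisible(x)
}
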