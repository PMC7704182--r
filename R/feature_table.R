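#' Construct a subject-by-feature table
#'
#' A `feature_table` holds one row per subject and one column per named
#' metabolite feature.  Missing measurements are `NA` in the value matrix;
#' all non-missing entries must be finite.  Column names normally come from
#' [mrs_schema()], but any subset (e.g. a selected panel) is allowed so the
#' same container flows through screening, feature selection and
#' classification.
#'
#' @param values Numeric matrix, subjects in rows, features in columns.
#'   Column names are required; `NA` marks a missing measurement.
#' @param subject_ids Optional character vector of row identifiers
#'   (defaults to existing rownames, else `S001`, `S002`, ...).
#' @param check_schema If `TRUE`, every column name must resolve in the
#'   canonical 117-feature schema.
#' @return An object of class `feature_table`: list with `values` (the
#'   matrix, rownames = subject ids) and `feature_names`.
#' @export
feature_table <- function(values, subject_ids = NULL, check_schema = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("feature_table needs at least one subject row")
  if (is.null(colnames(values))) stop("feature_table values need column names")
  if (anyDuplicated(colnames(values)))
    stop("duplicated feature columns: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) stop("non-finite (non-NA) values in feature table")
  if (check_schema) {
    unknown <- setdiff(colnames(values), mrs_schema()$feature_names)
    if (length(unknown))
      stop("unknown feature columns: ", paste(unknown, collapse = ", "))
  }
  if (is.null(subject_ids)) subject_ids <- rownames(values)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(values)))
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length does not match row count")
  rownames(values) <- subject_ids
  structure(list(values = values, feature_names = colnames(values)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  v <- x$values
  cat("feature_table:", nrow(v), "subjects x", ncol(v), "features;",
      sum(is.na(v)), "missing cells\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Coerce labels to the +1/-1 cohort coding
#'
#' Diagnosis labels are coded +1 for NPSLE (the positive class) and -1 for
#' healthy controls.  Accepts numeric `+1/-1`, `1/0`, or the strings
#' `"NPSLE"`/`"HC"` (case-insensitive).
#'
#' @param labels Vector of per-subject labels.
#' @return Integer vector in `{-1, +1}`.
#' @export
as_cohort_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lab <- toupper(trimws(labels))
    out <- ifelse(lab %in% c("NPSLE", "+1", "1", "POS"), 1L,
                  ifelse(lab %in% c("HC", "-1", "NEG", "0"), -1L, NA_integer_))
  } else {
    labels <- as.numeric(labels)
    out <- ifelse(labels > 0, 1L, ifelse(labels %in% c(-1, 0), -1L, NA_integer_))
    out[!labels %in% c(-1, 0, 1)] <- NA_integer_
  }
  if (anyNA(out))
    stop("unmappable diagnosis labels: ",
         paste(unique(labels[is.na(out)]), collapse = ", "))
  as.integer(out)
}

#' Read a delimited subject-by-feature table with diagnosis labels
#'
#' Reads UTF-8 delimited text (comma or tab, auto-detected from the header
#' line), one row per subject, with a mandatory header naming features in
#' the `REGION.MEASURE` grammar.  Empty cells and a configurable sentinel
#' become missing values.  Columns are reordered to canonical schema order.
#'
#' @param path Path to the file.
#' @param label_column Name of the diagnosis column (default `"diagnosis"`;
#'   values `NPSLE`/`HC` or `+1`/`-1`).
#' @param na Missing-value sentinel(s) in addition to the empty cell.
#' @return List with `table` (a [feature_table]) and `labels` (+1/-1
#'   integer vector).
#' @export
read_feature_table <- function(path, label_column = "diagnosis", na = "NA") {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("", na), check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path)
  labels <- as_cohort_labels(df[[label_column]])
  df[[label_column]] <- NULL
  subject_ids <- NULL
  if ("subject_id" %in% names(df)) {
    subject_ids <- as.character(df$subject_id)
    df$subject_id <- NULL
  }
  schema <- mrs_schema()
  unknown <- setdiff(names(df), schema$feature_names)
  if (length(unknown))
    stop("unknown feature columns: ", paste(unknown, collapse = ", "))
  for (j in names(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(parsed))
      if (length(bad))
        stop("non-numeric value '", col[bad[1]], "' at row ", bad[1],
             ", column '", j, "'")
      df[[j]] <- parsed
    }
  }
  ord <- intersect(schema$feature_names, names(df))
  values <- as.matrix(df[, ord, drop = FALSE])
  list(table = feature_table(values, subject_ids, check_schema = TRUE),
       labels = labels)
}

#' Write a feature table (and labels) as delimited text
#'
#' Inverse of [read_feature_table()]: missing cells are written as the
#' sentinel, and `subject_id` / label columns are prepended.
#'
#' @param table A [feature_table].
#' @param path Output path.
#' @param labels Optional +1/-1 labels, written as `NPSLE`/`HC`.
#' @param label_column Label column name.
#' @param sep Field separator (`","` or `"\t"`).
#' @param na Sentinel written for missing cells.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, labels = NULL,
                                label_column = "diagnosis", sep = ",",
                                na = "NA") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$values, check.names = FALSE)
  df <- cbind(data.frame(subject_id = rownames(table$values),
                         stringsAsFactors = FALSE), df)
  if (!is.null(labels)) {
    labels <- as_cohort_labels(labels)
    if (length(labels) != nrow(table$values))
      stop("labels length does not match table rows")
    df[[label_column]] <- ifelse(labels > 0, "NPSLE", "HC")
  }
  utils::write.table(df, path, sep = sep, na = na, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a feature table against the canonical schema
#'
#' Pure reporting: the input is never modified and no error is thrown.
#'
#' @param table A [feature_table] (or bare named matrix).
#' @return A list of class `table_validation`: `n_features_found` (count of
#'   columns resolving in the schema), `unknown_columns`,
#'   `duplicate_columns`, and `missing_fraction` (named per-feature
#'   fraction of missing cells).
#' @export
validate_feature_table <- function(table) {
  values <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  cn <- colnames(values)
  schema <- mrs_schema()
  structure(list(
    n_features_found = sum(unique(cn) %in% schema$feature_names),
    unknown_columns = setdiff(cn, schema$feature_names),
    duplicate_columns = unique(cn[duplicated(cn)]),
    missing_fraction = colMeans(is.na(values))
  ), class = "table_validation")
}

#' @export
print.table_validation <- function(x, ...) {
  cat("table_validation:", x$n_features_found, "schema features;",
      length(x$unknown_columns), "unknown,",
      length(x$duplicate_columns), "duplicated columns; max missing fraction",
      format(max(c(0, x$missing_fraction)), digits = 3), "\n")
  invisible(x)
}
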