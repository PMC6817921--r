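#' Read a two-class dataset from CSV
#'
#' Reads a comma-separated file with a header row, drops every row with a
#' missing attribute value (empty cell, `NA`, `?` or `NaN` — the sentinels
#' used by UCI repository files), and maps the label column to a binary
#' class.  All non-label columns must be numeric after the missing rows are
#' removed.
#'
#' @param path Path to a CSV file.
#' @param label_column Name of the label column (default `"class"`).
#' @param positive_label Label value of the positive (minority/case) class;
#'   when `NULL` the minority class is used.
#' @param na_strings Values treated as missing.
#' @return A [tabular_dataset()]; its `n_dropped` element records how many
#'   rows were discarded for missing values.
#' @export
read_dataset <- function(path, label_column = "class", positive_label = NULL,
                         na_strings = c("", "NA", "?", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, na.strings = na_strings, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in header", call. = FALSE)
  }
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("zero rows remain after dropping missing values",
                           call. = FALSE)
  labels <- df[[label_column]]
  feat <- df[setdiff(names(df), label_column)]
  if (ncol(feat) == 0L) stop("no feature columns", call. = FALSE)
  num <- vapply(feat, is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric feature column(s): ",
         paste(names(feat)[!num], collapse = ", "), call. = FALSE)
  }
  feat <- as.matrix(feat)
  rownames(feat) <- NULL
  tabular_dataset(feat, labels, positive = positive_label,
                  label_column = label_column, n_dropped = n_dropped)
}

#' Write a dataset to CSV
#'
#' Round-trips with [read_dataset()]: labels and feature names exactly,
#' feature values to full double precision (15 significant digits).
#'
#' @param ds A [tabular_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (ncol(ds$features) == 0L) stop("dataset has no feature columns", call. = FALSE)
  df <- as.data.frame(ds$features)
  df[[ds$label_column]] <- as.character(ds$labels)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified k-fold assignment
#'
#' Assigns every row to one of `k_folds` folds so that per-fold class counts
#' differ by at most one within each class.  Deterministic given `seed`.
#'
#' @param ds A [tabular_dataset()].
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: list with `fold` (integer in
#'   `1..k_folds` per row), `k_folds` and `seed`.
#' @export
stratified_kfold <- function(ds, k_folds = 10L, seed = 1L) {
  stopifnot(inherits(ds, "tabular_dataset"), k_folds >= 2L)
  cnt <- class_counts(ds)
  if (any(cnt < k_folds)) {
    stop("each class needs at least k_folds = ", k_folds,
         " members (counts: ", paste(cnt, collapse = "/"), ")", call. = FALSE)
  }
  fold <- integer(nrow(ds$features))
  withr::with_seed(seed, {
    for (lv in levels(ds$labels)) {
      idx <- which(ds$labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  structure(list(fold = fold, k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "fold_assignment")
}
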