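#' Construct a two-class tabular dataset
#'
#' The container passed between every stage of the package: a numeric feature
#' matrix plus a binary label vector.  The *positive* class is the class of
#' interest (in clinical screening data, the cancer / minority class); the
#' other class is *negative*.
#'
#' @param features Numeric matrix, `n` rows by `D` feature columns.
#' @param labels Vector of length `n` with at most two distinct values.
#' @param positive The label value treated as the positive class.  Defaults to
#'   the minority class (ties broken towards the later value in sort order).
#' @param label_column Name used for the label column when written to CSV.
#' @param n_dropped Number of rows removed upstream (e.g. for missing values).
#'
#' @return An object of class `tabular_dataset`: a list with elements
#'   `features` (matrix), `labels` (factor with the positive class as the
#'   second level), `positive`, `negative`, `label_column` and `n_dropped`.
#' @export
tabular_dataset <- function(features, labels, positive = NULL,
                            label_column = "class", n_dropped = 0L) {
  features <- as.matrix(features)
  if (!is.numeric(features)) {
    stop("all feature columns must be numeric", call. = FALSE)
  }
  if (nrow(features) != length(labels)) {
    stop("number of feature rows and labels differ", call. = FALSE)
  }
  if (is.null(colnames(features)) && ncol(features) > 0L) {
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  }
  vals <- sort(unique(as.character(labels)))
  if (length(vals) > 2L) {
    stop("more than two classes: ", paste(vals, collapse = ", "), call. = FALSE)
  }
  if (length(vals) == 0L) stop("dataset has zero rows", call. = FALSE)
  labels <- as.character(labels)
  if (is.null(positive)) {
    if (length(vals) == 1L) {
      positive <- vals
    } else {
      cnt <- table(factor(labels, levels = vals))
      # minority class is positive; tie -> second value in sort order
      positive <- if (cnt[[1L]] < cnt[[2L]]) vals[1L] else vals[2L]
    }
  } else {
    positive <- as.character(positive)
    if (!positive %in% vals) {
      stop("positive label '", positive, "' not present in data", call. = FALSE)
    }
  }
  negative <- setdiff(vals, positive)
  if (length(negative) == 0L) negative <- NA_character_
  structure(
    list(
      features = features,
      labels = factor(labels, levels = c(negative[!is.na(negative)], positive)),
      positive = positive,
      negative = negative,
      label_column = label_column,
      n_dropped = as.integer(n_dropped)
    ),
    class = "tabular_dataset"
  )
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cnt <- class_counts(x)
  cat(sprintf(
    "<tabular_dataset> %d rows, %d features; positive='%s' (%d), negative='%s' (%d)\n",
    nrow(x$features), ncol(x$features), x$positive, cnt[["positive"]],
    if (is.na(x$negative)) "<absent>" else x$negative, cnt[["negative"]]
  ))
  if (x$n_dropped > 0L) {
    cat(sprintf("  %d rows dropped for missing values at read time\n", x$n_dropped))
  }
  invisible(x)
}

#' Per-class row counts
#'
#' @param ds A [tabular_dataset()].
#' @return Named integer vector with elements `negative` and `positive`.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "tabular_dataset"))
  pos <- sum(ds$labels == ds$positive)
  c(negative = nrow(ds$features) - pos, positive = pos)
}

#' Logical mask of positive-class rows
#' @param ds A [tabular_dataset()].
#' @return Logical vector of length `n`.
#' @export
positive_mask <- function(ds) {
  ds$labels == ds$positive
}

#' Row subset of a dataset
#'
#' Keeps class polarity and metadata; the result may be degenerate (one class).
#'
#' @param ds A [tabular_dataset()].
#' @param idx Integer row indices.
#' @return A [tabular_dataset()] with the selected rows, in `idx` order.
#' @export
subset_rows <- function(ds, idx) {
  stopifnot(inherits(ds, "tabular_dataset"))
  labs <- as.character(ds$labels[idx])
  pos <- if (ds$positive %in% labs) ds$positive else unique(labs)[1L]
  tabular_dataset(ds$features[idx, , drop = FALSE], labs,
                  positive = pos, label_column = ds$label_column)
}

#' Imbalance ratio of a two-class dataset
#'
#' Majority-class count divided by minority-class count; always `>= 1`.
#'
#' @param ds A [tabular_dataset()].
#' @return A positive number.
#' @export
#' @examples
#' ds <- make_imbalanced(n = 300, ir = 5, dims = 2, seed = 1)
#' imbalance_ratio(ds)  # 5
imbalance_ratio <- function(ds) {
  cnt <- class_counts(ds)
  if (any(cnt == 0L)) {
    stop("imbalance ratio undefined: one class is absent", call. = FALSE)
  }
  max(cnt) / min(cnt)
}

#' Min-max scale the features of a dataset
#'
#' K-means distances are scale-sensitive; by default the package uses features
#' as-is, but this helper rescales every column to `[0, 1]` for callers who
#' want scale-free thresholds.  Constant columns map to 0.
#'
#' @param ds A [tabular_dataset()].
#' @return A [tabular_dataset()] with rescaled features.
#' @export
scale_minmax <- function(ds) {
  stopifnot(inherits(ds, "tabular_dataset"))
  x <- ds$features
  rng <- apply(x, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  ds$features <- sweep(sweep(x, 2L, rng[1L, ], "-"), 2L, span, "/")
  ds
}
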