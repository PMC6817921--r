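#' Random undersampling to exact balance
#'
#' Keeps every minority-class row and draws, without replacement, a majority
#' subset of the same size.  No row is fabricated; the output is exactly
#' balanced and deterministic given `seed`.
#'
#' @param ds A [tabular_dataset()] with both classes present.
#' @param seed Integer seed.
#' @return A balanced [tabular_dataset()] whose rows are a subset of `ds`.
#' @export
random_undersample <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "tabular_dataset"))
  cnt <- class_counts(ds)
  if (any(cnt == 0L)) stop("both classes must be present", call. = FALSE)
  pos <- positive_mask(ds)
  min_is_pos <- cnt[["positive"]] <= cnt[["negative"]]
  min_idx <- which(pos == min_is_pos)
  maj_idx <- which(pos != min_is_pos)
  keep_maj <- withr::with_seed(seed, sample(maj_idx, length(min_idx)))
  subset_rows(ds, sort(c(min_idx, keep_maj)))
}

#' SMOTE parameters
#'
#' @param over_pct Synthetic minority points to create, as a percentage of the
#'   original minority count; must be a positive multiple of 100 (each 100
#'   yields one synthetic copy per minority point).  Default 100.
#' @param under_pct Majority rows retained, as a percentage of the *number of
#'   synthetic points created*.  Default 300.
#' @param k_neighbors Minority nearest neighbours to interpolate towards
#'   (default 5).
#' @param seed Integer seed.
#' @return A list of class `smote_params`.
#' @export
smote_params <- function(over_pct = 100L, under_pct = 300L, k_neighbors = 5L,
                         seed = 1L) {
  stopifnot(over_pct >= 100L, over_pct %% 100L == 0L,
            under_pct > 0L, k_neighbors >= 1L)
  structure(list(over_pct = as.integer(over_pct),
                 under_pct = as.integer(under_pct),
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "smote_params")
}

#' SMOTE: synthetic minority oversampling with majority undersampling
#'
#' For each minority row `x`, `over_pct / 100` synthetic rows are created as
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and `x_nn` one of the
#' `k_neighbors` nearest minority rows (Euclidean distance, ties broken by
#' row index).  The majority class is then downsampled (without replacement)
#' to `under_pct / 100` times the number of synthetic rows, capped at the
#' available majority count.
#'
#' @param ds A [tabular_dataset()].
#' @param params A [smote_params()] object.
#' @return A [tabular_dataset()] containing the original minority rows, the
#'   synthetic minority rows, and the retained majority rows.
#' @export
smote <- function(ds, params = smote_params()) {
  stopifnot(inherits(ds, "tabular_dataset"), inherits(params, "smote_params"))
  cnt <- class_counts(ds)
  if (any(cnt == 0L)) stop("both classes must be present", call. = FALSE)
  pos <- positive_mask(ds)
  min_is_pos <- cnt[["positive"]] <= cnt[["negative"]]
  min_idx <- which(pos == min_is_pos)
  maj_idx <- which(pos != min_is_pos)
  if (length(min_idx) <= params$k_neighbors) {
    stop("minority count (", length(min_idx), ") must exceed k_neighbors (",
         params$k_neighbors, ")", call. = FALSE)
  }
  Xmin <- ds$features[min_idx, , drop = FALSE]
  min_label <- as.character(ds$labels[min_idx[1L]])
  maj_label <- as.character(ds$labels[maj_idx[1L]])
  n_copies <- params$over_pct %/% 100L

  out <- withr::with_seed(params$seed, {
    nn <- .knn_indices(Xmin, params$k_neighbors)
    synth <- .smote_synthesize(Xmin, nn, n_copies)
    n_keep <- min(length(maj_idx),
                  round(params$under_pct / 100 * nrow(synth)))
    keep_maj <- sort(sample(maj_idx, n_keep))
    list(synth = synth, keep_maj = keep_maj)
  })

  feats <- rbind(ds$features[min_idx, , drop = FALSE], out$synth,
                 ds$features[out$keep_maj, , drop = FALSE])
  labels <- c(rep(min_label, length(min_idx) + nrow(out$synth)),
              rep(maj_label, length(out$keep_maj)))
  tabular_dataset(feats, labels, positive = ds$positive,
                  label_column = ds$label_column)
}

# k nearest neighbours among the rows of X (self excluded), ties by row index.
.knn_indices <- function(X, k) {
  n <- nrow(X)
  k <- min(k, n - 1L)
  sq <- .sqdist(X, X)
  res <- vapply(seq_len(n), function(i) {
    ord <- order(sq[i, ], seq_len(n))
    ord[ord != i][seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

# n_copies synthetic rows per base row, interpolated towards a random
# neighbour.  Consumes RNG; caller seeds.
.smote_synthesize <- function(Xmin, nn, n_copies) {
  n <- nrow(Xmin)
  k <- ncol(nn)
  base <- rep(seq_len(n), each = n_copies)
  pick <- nn[cbind(base, sample.int(k, length(base), replace = TRUE))]
  u <- stats::runif(length(base))
  Xmin[base, , drop = FALSE] +
    u * (Xmin[pick, , drop = FALSE] - Xmin[base, , drop = FALSE])
}
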