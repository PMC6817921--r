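#' Parameters for boundary-instance selection
#'
#' @param eta Positive multiplier on the average centroid distance forming the
#'   selection threshold.  Typical values for UCI benchmark data lie in
#'   0.25–1.6; default 1.
#' @param K Number of clusters (default 2, one per side of a two-class task).
#' @param rule `"boundary"` keeps points whose centroid distance is at least
#'   `eta` times the reference average (far-from-centroid points, presumed
#'   near the class boundary; the default).  `"interior"` keeps points whose
#'   distance is *below* the threshold instead.
#' @param scope Reference average: `"per_cluster"` (each cluster's own mean
#'   distance, default) or `"global"` (one dataset-wide mean).
#' @param cluster_on `"all_data"` clusters the pooled feature matrix
#'   (default); `"per_class"` clusters each class separately.
#' @param balance How to equalise the per-class selected counts:
#'   `"trim"` (default) first relaxes the threshold once (`eta/2`) for the
#'   deficient class if counts are unequal, then trims the larger class to the
#'   smaller count, dropping the least informative points first;
#'   `"relax_eta"` allows up to two halvings before trimming; `"none"` leaves
#'   the raw selection.
#' @param seed Integer seed (clustering initialisation).
#' @param nstart Random restarts for the internal K-means.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(eta = 1, K = 2L,
                             rule = c("boundary", "interior"),
                             scope = c("per_cluster", "global"),
                             cluster_on = c("all_data", "per_class"),
                             balance = c("trim", "relax_eta", "none"),
                             seed = 1L, nstart = 1L) {
  stopifnot(eta > 0, K >= 1L)
  structure(
    list(eta = eta, K = as.integer(K), rule = match.arg(rule),
         scope = match.arg(scope), cluster_on = match.arg(cluster_on),
         balance = match.arg(balance), seed = as.integer(seed),
         nstart = as.integer(nstart)),
    class = "selection_params"
  )
}

#' Select informative (boundary) instances via K-means distances
#'
#' The package's core undersampling step.  The feature matrix is clustered
#' with K-means (labels are never consulted before balancing), the Euclidean
#' distance of every point to its cluster centroid is computed, and points
#' are kept when their distance passes `eta` times the reference average
#' distance of their cluster.  Under the default `"boundary"` rule the far
#' points — those near the cluster border, presumed most informative for
#' classification — are kept and the interior points are rejected; the
#' selected set is then balanced across the two classes so it can serve as a
#' training subset, and the rejected remainder can be used as a held-out test
#' subset.
#'
#' @param ds A [tabular_dataset()] with both classes present.
#' @param params A [selection_params()] object.
#' @return An object of class `selection_result`: `selected_idx` and
#'   `rejected_idx` (a partition of `1..n`), `eta_effective` (named per-class
#'   thresholds actually applied), `per_class_selected` counts, `balanced`
#'   flag, and the internal `distance`, `cluster` and `d_avg` vectors.
#' @export
#' @examples
#' ds <- make_imbalanced(n = 200, ir = 4, dims = 2, separation = 4, seed = 1)
#' sel <- select_informative(ds, selection_params(eta = 1, seed = 1))
#' sel$per_class_selected  # equal counts
select_informative <- function(ds, params = selection_params()) {
  stopifnot(inherits(ds, "tabular_dataset"), inherits(params, "selection_params"))
  cnt <- class_counts(ds)
  if (any(cnt == 0L)) stop("both classes must be present", call. = FALSE)
  n <- nrow(ds$features)

  if (params$cluster_on == "all_data") {
    model <- fit_kmeans(ds$features, K = min(params$K, n), seed = params$seed,
                        nstart = params$nstart)
    d <- model$point_distance
    clus <- model$assignment
    davg <- .ref_average(d, clus, params$scope)
  } else {
    # cluster each class separately; cluster ids offset so they stay distinct
    d <- numeric(n)
    clus <- integer(n)
    davg <- numeric(n)
    off <- 0L
    for (lv in levels(ds$labels)) {
      idx <- which(ds$labels == lv)
      m <- fit_kmeans(ds$features[idx, , drop = FALSE],
                      K = min(params$K, length(idx)), seed = params$seed,
                      nstart = params$nstart)
      d[idx] <- m$point_distance
      clus[idx] <- m$assignment + off
      ref <- .ref_average(m$point_distance, m$assignment, params$scope)
      davg[idx] <- ref[m$assignment]
      off <- off + nrow(m$centroids)
    }
  }
  if (params$cluster_on == "all_data") davg <- davg[clus]

  pos <- positive_mask(ds)
  keep <- .threshold_keep(d, davg, params$eta, params$rule)

  eta_eff <- c(positive = params$eta, negative = params$eta)
  if (params$balance == "none") {
    sel <- which(keep)
  } else {
    max_halvings <- if (params$balance == "trim") 1L else 2L
    bal <- .balance_selection(keep, d, davg, pos, params$eta, params$rule,
                              max_halvings)
    sel <- bal$selected
    eta_eff <- bal$eta_effective
  }
  if (length(sel) == 0L) {
    stop("degenerate selection: no instance passes the threshold at eta = ",
         params$eta, call. = FALSE)
  }
  sel <- sort(sel)
  rej <- setdiff(seq_len(n), sel)
  structure(
    list(selected_idx = sel, rejected_idx = rej,
         eta_effective = eta_eff,
         per_class_selected = c(negative = sum(!pos[sel]), positive = sum(pos[sel])),
         balanced = sum(pos[sel]) == sum(!pos[sel]),
         distance = d, cluster = clus, d_avg = davg, params = params),
    class = "selection_result"
  )
}

.ref_average <- function(d, clus, scope) {
  if (scope == "global") {
    rep(sum(d) / length(d), max(clus))
  } else {
    sizes <- tabulate(clus)
    as.vector(rowsum(d, clus)) / sizes
  }
}

.threshold_keep <- function(d, davg, eta, rule) {
  if (rule == "boundary") d >= eta * davg else d < eta * davg
}

# Equalise per-class selected counts.  The deficient class's threshold is
# halved up to `max_halvings` times until it has at least as many candidates
# as the other class; both classes are then trimmed to the common count,
# dropping the least informative points first (smallest distance under the
# boundary rule, largest under the interior rule; ties -> lowest row index).
.balance_selection <- function(keep, d, davg, pos, eta, rule, max_halvings) {
  eta_cls <- c(positive = eta, negative = eta)
  cand <- list(positive = which(keep & pos), negative = which(keep & !pos))
  h <- 0L
  while (h < max_halvings) {
    np <- length(cand$positive); nn <- length(cand$negative)
    if (np == nn) break
    deficient <- if (np < nn) "positive" else "negative"
    if (length(cand[[deficient]]) >= max(np, nn)) break
    h <- h + 1L
    eta_cls[deficient] <- eta / 2^h
    mask <- if (deficient == "positive") pos else !pos
    cand[[deficient]] <-
      which(.threshold_keep(d, davg, eta_cls[deficient], rule) & mask)
    if (length(cand[[deficient]]) >= max(np, nn)) break
  }
  if (any(lengths(cand) == 0L)) {
    stop("degenerate selection: one class empty even at eta = ",
         signif(min(eta_cls), 4), call. = FALSE)
  }
  m <- min(lengths(cand))
  selected <- c(.keep_most_informative(cand$positive, d, rule, m),
                .keep_most_informative(cand$negative, d, rule, m))
  list(selected = selected, eta_effective = eta_cls)
}

.keep_most_informative <- function(idx, d, rule, m) {
  if (length(idx) <= m) return(idx)
  ord <- if (rule == "boundary") {
    order(-d[idx], idx)   # largest distance = most informative
  } else {
    order(d[idx], idx)    # interior rule: smallest distance most informative
  }
  idx[ord[seq_len(m)]]
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d selected (%d pos / %d neg%s), %d rejected; eta = %s\n",
    length(x$selected_idx), x$per_class_selected[["positive"]],
    x$per_class_selected[["negative"]],
    if (x$balanced) ", balanced" else "", length(x$rejected_idx),
    paste(sprintf("%s=%.3g", names(x$eta_effective), x$eta_effective),
          collapse = ", ")
  ))
  invisible(x)
}

#' Re-balance an existing selection
#'
#' `balance = "trim"` reduces the larger selected class to the smaller
#' class's count, dropping the least informative points first.
#' `balance = "relax_eta"` re-runs the deficient class's thresholding with
#' `eta` halved (at most twice) until it has enough candidates, then
#' equalises the counts.
#'
#' @param selection A [select_informative()] result.
#' @param ds The dataset the selection was computed on.
#' @param params A [selection_params()]; its `balance` element picks the mode.
#' @return An updated `selection_result` with equal per-class counts.
#' @export
rebalance <- function(selection, ds, params = selection$params) {
  stopifnot(inherits(selection, "selection_result"))
  pos <- positive_mask(ds)
  d <- selection$distance
  davg <- selection$d_avg
  sel <- selection$selected_idx
  if (params$balance == "none") return(selection)

  if (params$balance == "trim") {
    cand <- list(positive = sel[pos[sel]], negative = sel[!pos[sel]])
    if (any(lengths(cand) == 0L)) {
      stop("degenerate selection: cannot trim with an empty class", call. = FALSE)
    }
    m <- min(lengths(cand))
    new_sel <- c(.keep_most_informative(cand$positive, d, params$rule, m),
                 .keep_most_informative(cand$negative, d, params$rule, m))
    eta_eff <- selection$eta_effective
  } else {
    keep <- logical(length(d))
    keep[sel] <- TRUE
    bal <- .balance_selection(keep, d, davg, pos, params$eta, params$rule,
                              max_halvings = 2L)
    new_sel <- bal$selected
    eta_eff <- bal$eta_effective
  }
  new_sel <- sort(new_sel)
  selection$selected_idx <- new_sel
  selection$rejected_idx <- setdiff(seq_along(d), new_sel)
  selection$per_class_selected <- c(negative = sum(!pos[new_sel]),
                                    positive = sum(pos[new_sel]))
  selection$balanced <- TRUE
  selection$eta_effective <- eta_eff
  selection
}

#' Split a dataset into selected (train) and rejected (test) subsets
#'
#' @param ds A [tabular_dataset()].
#' @param selection A [select_informative()] result on `ds`.
#' @return List with elements `train` (rows at `selected_idx`) and `test`
#'   (rows at `rejected_idx`); together they reconstruct `ds`.
#' @export
split_train_test <- function(ds, selection) {
  stopifnot(inherits(ds, "tabular_dataset"), inherits(selection, "selection_result"))
  if (length(selection$rejected_idx) == 0L) {
    stop("empty test set: every row was selected", call. = FALSE)
  }
  list(train = subset_rows(ds, selection$selected_idx),
       test = subset_rows(ds, selection$rejected_idx))
}
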