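#' Gain-ratio decision tree (C4.5-style) for two classes
#'
#' Grows a binary tree on numeric features.  At each node every candidate
#' threshold (midpoint between consecutive distinct sorted values of a
#' feature) is scored by the gain ratio — information gain divided by split
#' information — computed from *weighted* class frequencies, so the tree can
#' serve as the weak learner inside a boosting loop.  Ties are broken towards
#' the lower feature index, then the lower threshold.  After growing, the
#' tree is simplified by pessimistic-error postpruning: a subtree is
#' collapsed to a leaf whenever the leaf's upper-confidence-bound error
#' estimate (confidence factor `pruning_cf`) does not exceed the subtree's.
#'
#' @param X Numeric matrix of features.
#' @param y Factor (or vector) of class labels with at most two levels.
#' @param sample_weights Non-negative case weights; default uniform.  They
#'   are rescaled internally so the total equals the row count, which keeps
#'   the pruning error estimates on a case-count scale.
#' @param min_leaf Minimum rows in each child of a split (default 2).
#' @param pruning_cf Confidence factor of the pessimistic pruning
#'   (default 0.25, the classical C4.5 value); `NA` disables pruning.
#' @return An object of class `decision_tree` with elements `root` (nested
#'   node list), `levels`, `n_leaves`, `min_leaf`, `pruning_cf`.
#' @export
#' @examples
#' X <- matrix(c(1, 2, 4, 5), ncol = 1)
#' y <- factor(c("a", "a", "b", "b"))
#' tr <- fit_tree(X, y)
#' predict(tr, matrix(c(0, 10), ncol = 1))
fit_tree <- function(X, y, sample_weights = NULL, min_leaf = 2L,
                     pruning_cf = 0.25) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 1L, ncol(X) >= 1L)
  y <- factor(y)
  if (nlevels(y) > 2L) stop("at most two classes supported", call. = FALSE)
  if (is.null(sample_weights)) sample_weights <- rep.int(1, n)
  if (any(sample_weights < 0) || sum(sample_weights) <= 0) {
    stop("sample weights must be non-negative with positive total", call. = FALSE)
  }
  w <- sample_weights / sum(sample_weights) * n  # case-count scale
  ybin <- as.integer(y)                          # 1 / 2
  root <- .grow_node(X, ybin, w, seq_len(n), nlevels(y), min_leaf)
  if (!is.na(pruning_cf)) root <- .prune_node(root, pruning_cf)
  structure(
    list(root = root, levels = levels(y), n_leaves = .count_leaves(root),
         min_leaf = as.integer(min_leaf), pruning_cf = pruning_cf,
         n_features = ncol(X)),
    class = "decision_tree"
  )
}

# Weighted two-class entropy in bits, from class-weight vector.
.entropy <- function(wc) {
  tot <- sum(wc)
  if (tot <= 0) return(0)
  p <- wc / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

.leaf_node <- function(wc) {
  tot <- sum(wc)
  prob <- if (tot > 0) wc / tot else rep(1 / length(wc), length(wc))
  # tie -> first level (the negative class by the package's ordering)
  list(leaf = TRUE, class = which.max(prob), prob = prob,
       n = tot, err = tot - max(wc))
}

.grow_node <- function(X, ybin, w, idx, n_levels, min_leaf) {
  wc <- vapply(seq_len(n_levels), function(l) sum(w[idx][ybin[idx] == l]),
               numeric(1L))
  if (n_levels == 1L || min(wc) <= 0 || length(idx) < 2L * min_leaf) {
    return(.leaf_node(wc))
  }
  best <- .best_split(X, ybin, w, idx, wc, min_leaf)
  if (is.null(best)) return(.leaf_node(wc))
  xv <- X[idx, best$feature]
  left <- idx[xv <= best$threshold]
  right <- idx[xv > best$threshold]
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       gain_ratio = best$gain_ratio,
       left = .grow_node(X, ybin, w, left, n_levels, min_leaf),
       right = .grow_node(X, ybin, w, right, n_levels, min_leaf),
       n = sum(wc), wc = wc, err = sum(wc) - max(wc))
}

# Best (feature, threshold) by gain ratio over all candidate midpoints.
# Returns NULL when no split has positive information gain.
.best_split <- function(X, ybin, w, idx, wc, min_leaf) {
  W <- sum(wc)
  H0 <- .entropy(wc)
  best <- NULL
  n_i <- length(idx)
  for (j in seq_len(ncol(X))) {
    xv <- X[idx, j]
    o <- order(xv)
    xs <- xv[o]
    ws <- w[idx][o]
    is_pos <- ybin[idx][o] == 2L
    cw <- cumsum(ws)
    cw2 <- cumsum(ws * is_pos)
    # cut after position i is valid when the value strictly increases and
    # both children satisfy the count-based min_leaf
    cuts <- which(xs[-n_i] < xs[-1L])
    cuts <- cuts[cuts >= min_leaf & cuts <= n_i - min_leaf]
    if (length(cuts) == 0L) next
    wl <- cw[cuts]
    wl_pos <- cw2[cuts]
    wr <- W - wl
    wr_pos <- cw2[n_i] - wl_pos
    Hl <- .entropy2(wl - wl_pos, wl_pos)
    Hr <- .entropy2(wr - wr_pos, wr_pos)
    gain <- H0 - (wl * Hl + wr * Hr) / W
    si <- .entropy2(wl, wr)  # split information
    ok <- gain > 1e-12 & si > 0
    if (!any(ok)) next
    gr <- ifelse(ok, gain / si, -Inf)
    i <- which.max(gr)  # ties -> lowest threshold
    if (is.null(best) || gr[i] > best$gain_ratio + 1e-12) {
      best <- list(feature = j,
                   threshold = (xs[cuts[i]] + xs[cuts[i] + 1L]) / 2,
                   gain_ratio = gr[i])
    }
  }
  best
}

# Vectorised two-class entropy from (negative, positive) weight vectors.
.entropy2 <- function(wn, wp) {
  tot <- wn + wp
  p <- numeric(length(tot))
  p[tot > 0] <- wp[tot > 0] / tot[tot > 0]
  term <- function(q) {
    r <- numeric(length(q))
    pos <- q > 0
    r[pos] <- -q[pos] * log2(q[pos])
    r
  }
  term(p) + term(1 - p)
}

# C4.5 pessimistic error: upper confidence bound on the error count of a
# leaf seeing E errors in N cases, at confidence factor cf.
.ucf_errors <- function(E, N, cf) {
  if (N <= 0) return(0)
  f <- E / N
  z <- stats::qnorm(1 - cf)
  ub <- (f + z^2 / (2 * N) +
           z * sqrt(f / N - f^2 / N + z^2 / (4 * N^2))) / (1 + z^2 / N)
  N * min(1, ub)
}

.prune_node <- function(node, cf) {
  if (node$leaf) {
    node$est_err <- .ucf_errors(node$err, node$n, cf)
    return(node)
  }
  node$left <- .prune_node(node$left, cf)
  node$right <- .prune_node(node$right, cf)
  subtree_est <- node$left$est_err + node$right$est_err
  leaf_est <- .ucf_errors(node$err, node$n, cf)
  if (leaf_est <= subtree_est + 1e-9) {
    pruned <- .leaf_node(node$wc)
    pruned$est_err <- leaf_est
    return(pruned)
  }
  node$est_err <- subtree_est
  node
}

.count_leaves <- function(node) {
  if (node$leaf) 1L else .count_leaves(node$left) + .count_leaves(node$right)
}

#' Predict classes or class probabilities from a decision tree
#'
#' @param object A [fit_tree()] model.
#' @param newdata Numeric matrix with the same number of columns as training.
#' @param type `"class"` (default) or `"prob"` (positive-class probability,
#'   i.e. of the second factor level).
#' @param ... Unused.
#' @return Factor of predicted labels, or numeric vector of probabilities.
#' @export
predict.decision_tree <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("dimension mismatch: model expects D=", object$n_features, call. = FALSE)
  }
  n <- nrow(newdata)
  cls <- integer(n)
  prob <- numeric(n)
  descend <- function(node, rows) {
    if (length(rows) == 0L) return()
    if (node$leaf) {
      cls[rows] <<- node$class
      prob[rows] <<- if (length(node$prob) >= 2L) node$prob[2L] else
        as.numeric(node$class == 2L)
      return()
    }
    go_left <- newdata[rows, node$feature] <= node$threshold
    descend(node$left, rows[go_left])
    descend(node$right, rows[!go_left])
  }
  descend(object$root, seq_len(n))
  if (type == "prob") return(prob)
  factor(object$levels[cls], levels = object$levels)
}
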