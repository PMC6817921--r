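#' Lloyd-style K-means with centroid-distance bookkeeping
#'
#' Classical Lloyd iteration: centroids are initialised by drawing `K`
#' distinct rows of `X` at random, every point is assigned to its nearest
#' centroid under Euclidean distance (ties broken towards the lower cluster
#' index), centroids are recomputed as coordinate-wise means, and the loop
#' stops when cluster membership stabilises, the largest centroid shift drops
#' below `tol`, or `max_iter` is reached.  Empty clusters are repaired by
#' promoting the point farthest from its current centroid to be the empty
#' cluster's centroid.
#'
#' The reported `inertia` is, by default, the *sum of unsquared Euclidean
#' distances* of each point to its centroid (the form consumed by the
#' undersampler's average-distance threshold); set `objective = "squared"`
#' for the classical within-cluster sum of squares.  The internal Lloyd
#' updates always minimise the squared objective, whose per-iteration values
#' are recorded in `obj_history` (monotone non-increasing).
#'
#' @param X Numeric matrix, `n` rows by `D` columns.
#' @param K Number of clusters, `1 <= K <= n`.
#' @param seed Integer seed for the random-row initialisation.
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @param tol Centroid-shift convergence tolerance (default 1e-6).
#' @param nstart Number of random restarts; the run with the lowest squared
#'   objective is kept.
#' @param objective `"euclidean"` (sum of distances, default) or `"squared"`.
#' @param init Optional `K x D` matrix of starting centroids, bypassing the
#'   random initialisation.
#'
#' @return An object of class `cluster_model`: `centroids` (`K x D`),
#'   `assignment` (integer in `1..K` per row), `point_distance` (Euclidean
#'   distance of each point to its own centroid), `inertia`, `n_iter`,
#'   `obj_history`, `seed`, `objective`.
#' @export
#' @examples
#' X <- rbind(matrix(0, 3, 2), matrix(10, 3, 2))
#' m <- fit_kmeans(X, K = 2, seed = 1)
#' m$inertia  # 0: both blobs collapse onto their centroids
fit_kmeans <- function(X, K, seed = 1L, max_iter = 300L, tol = 1e-6,
                       nstart = 1L, objective = c("euclidean", "squared"),
                       init = NULL) {
  objective <- match.arg(objective)
  X <- as.matrix(X)
  n <- nrow(X)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (K < 1L || K > n) stop("K must be in [1, n]", call. = FALSE)
  stopifnot(max_iter >= 1L, tol >= 0)

  runs <- if (is.null(init)) nstart else 1L
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(runs)) {
      cent <- if (is.null(init)) X[sample.int(n, K), , drop = FALSE] else as.matrix(init)
      fit <- .lloyd(X, cent, max_iter, tol)
      if (is.null(best) || fit$sq_obj < best$sq_obj) best <- fit
    }
  })

  d <- sqrt(.sqdist_own(X, best$centroids, best$assignment))
  inertia <- if (objective == "euclidean") sum(d) else sum(d^2)
  structure(
    list(centroids = best$centroids, assignment = best$assignment,
         point_distance = d, inertia = inertia, n_iter = best$n_iter,
         obj_history = best$obj_history, seed = as.integer(seed),
         objective = objective),
    class = "cluster_model"
  )
}

# One Lloyd run from given starting centroids.
.lloyd <- function(X, cent, max_iter, tol) {
  n <- nrow(X)
  K <- nrow(cent)
  assign_old <- rep.int(0L, n)
  obj_history <- numeric(0L)
  for (it in seq_len(max_iter)) {
    st <- .assign_repair(X, cent)
    cent <- st$cent
    asg <- st$asg
    obj_history <- c(obj_history, st$obj)
    new_cent <- rowsum(X, asg) / as.vector(table(factor(asg, levels = seq_len(K))))
    shift <- sqrt(max(rowSums((new_cent - cent)^2)))
    stable <- identical(asg, assign_old)
    cent <- new_cent
    assign_old <- asg
    if (stable || shift < tol) break
  }
  st <- .assign_repair(X, cent)
  list(centroids = st$cent, assignment = st$asg, sq_obj = st$obj,
       n_iter = it, obj_history = obj_history)
}

# Nearest-centroid assignment (ties -> lowest cluster index) with
# empty-cluster repair: the point farthest from its own centroid is promoted
# to be the empty cluster's centroid and force-assigned to it.
.assign_repair <- function(X, cent) {
  n <- nrow(X)
  K <- nrow(cent)
  sq <- .sqdist(X, cent)
  asg <- max.col(-sq, ties.method = "first")
  pinned <- rep.int(FALSE, n)
  for (pass in seq_len(K)) {
    empty <- setdiff(seq_len(K), unique(asg))
    if (length(empty) == 0L) break
    own <- sq[cbind(seq_len(n), asg)]
    own[pinned] <- -Inf
    for (e in empty) {
      far <- which.max(own)
      cent[e, ] <- X[far, ]
      asg[far] <- e
      pinned[far] <- TRUE
      own[far] <- -Inf
    }
    sq <- .sqdist(X, cent)
    # re-assign the unpinned points against the repaired centroids,
    # keeping promoted points in their new clusters
    free <- max.col(-sq, ties.method = "first")
    asg[!pinned] <- free[!pinned]
  }
  list(cent = cent, asg = asg, obj = sum(sq[cbind(seq_len(n), asg)]))
}

# n x K matrix of squared Euclidean distances (clamped at 0).
.sqdist <- function(X, C) {
  sq <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  sq[sq < 0] <- 0
  sq
}

.sqdist_own <- function(X, C, asg) {
  unname(rowSums((X - C[asg, , drop = FALSE])^2))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K=%d, n=%d, inertia=%.4g (%s), %d iteration(s)\n",
              nrow(x$centroids), length(x$assignment), x$inertia,
              x$objective, x$n_iter))
  invisible(x)
}

#' Euclidean distance of each point to its assigned centroid
#'
#' @param model A fitted [fit_kmeans()] model.
#' @param X The matrix the model was fitted on (same rows and dimension).
#' @return Numeric vector of length `n`.
#' @export
point_distances <- function(model, X) {
  stopifnot(inherits(model, "cluster_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$centroids)) {
    stop("dimension mismatch: model has D=", ncol(model$centroids), call. = FALSE)
  }
  if (nrow(X) != length(model$assignment)) {
    stop("row count does not match the fitted assignment", call. = FALSE)
  }
  sqrt(.sqdist_own(X, model$centroids, model$assignment))
}

#' Average centroid distance, per cluster or global
#'
#' `scope = "per_cluster"` returns the mean member-to-centroid distance of
#' each cluster (the threshold basis used by the undersampler);
#' `scope = "global"` returns the single value: total distance over all
#' points divided by `N`.
#'
#' @param model A fitted [fit_kmeans()] model.
#' @param X The matrix the model was fitted on.
#' @param scope `"per_cluster"` or `"global"`.
#' @return Numeric vector (length `K`) or single number.
#' @export
average_distance <- function(model, X, scope = c("per_cluster", "global")) {
  scope <- match.arg(scope)
  d <- point_distances(model, X)
  if (scope == "global") return(sum(d) / length(d))
  K <- nrow(model$centroids)
  sizes <- tabulate(model$assignment, nbins = K)
  if (any(sizes == 0L)) stop("empty cluster in per-cluster scope", call. = FALSE)
  as.vector(rowsum(d, model$assignment)) / sizes
}
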