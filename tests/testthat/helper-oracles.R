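# Independent brute-force oracles used across the suite.  These are written
# directly from first principles and never call the package's own internals.

# Exhaustive minimum of the within-cluster sum of squares over all 2-way
# partitions (both clusters non-empty) of <= ~12 points.
brute_best_partition <- function(X, K = 2L) {
  stopifnot(K == 2L)
  n <- nrow(X)
  best_obj <- Inf
  best_asg <- NULL
  for (code in 1:(2^(n - 1L) - 1L)) {  # fix point 1 in cluster 1; skip empty
    asg <- c(1L, as.integer(intToBits(code)[1:(n - 1L)]) + 1L)
    obj <- 0
    for (k in 1:2) {
      rows <- X[asg == k, , drop = FALSE]
      ctr <- colMeans(rows)
      obj <- obj + sum(sweep(rows, 2L, ctr)^2)
    }
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_asg <- asg
    }
  }
  list(assignment = best_asg, objective = best_obj)
}

# Squared-objective of a given 2-partition (cluster centres = means).
partition_objective <- function(X, asg) {
  obj <- 0
  for (k in unique(asg)) {
    rows <- X[asg == k, , drop = FALSE]
    ctr <- colMeans(rows)
    obj <- obj + sum(sweep(rows, 2L, ctr)^2)
  }
  obj
}

same_partition <- function(a, b) {
  identical(a, b) || identical(a, 3L - b)  # 2-cluster labels up to swap
}

# Plain per-point Euclidean distance loop (oracle for point_distances).
loop_distances <- function(X, centroids, assignment) {
  vapply(seq_len(nrow(X)), function(i) {
    sqrt(sum((X[i, ] - centroids[assignment[i], ])^2))
  }, numeric(1L))
}

# Direct filter-then-balance loop coded from the selection rule: keep points
# with distance >= eta * their cluster's mean distance (boundary) or < it
# (interior); no balancing.
loop_select <- function(d, clus, eta, rule = "boundary") {
  davg <- tapply(d, clus, mean)
  keep <- logical(length(d))
  for (i in seq_along(d)) {
    thr <- eta * davg[[as.character(clus[i])]]
    keep[i] <- if (rule == "boundary") d[i] >= thr else d[i] < thr
  }
  which(keep)
}

# Exhaustive gain-ratio split search (oracle for the tree's root split).
loop_best_split <- function(X, y, w = rep(1, nrow(X))) {
  ent <- function(wpos, wneg) {
    tot <- wpos + wneg
    if (tot <= 0) return(0)
    p <- c(wpos, wneg) / tot
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  is_pos <- y == levels(factor(y))[2L]
  W <- sum(w)
  H0 <- ent(sum(w[is_pos]), sum(w[!is_pos]))
  best <- list(gr = -Inf, feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2L) next
    for (t in (vals[-1] + vals[-length(vals)]) / 2) {
      l <- X[, j] <= t
      wl <- sum(w[l]); wr <- W - wl
      gain <- H0 - (wl * ent(sum(w[l & is_pos]), sum(w[l & !is_pos])) +
                    wr * ent(sum(w[!l & is_pos]), sum(w[!l & !is_pos]))) / W
      si <- ent(wl, wr)
      if (gain > 1e-12 && si > 0) {
        gr <- gain / si
        if (gr > best$gr + 1e-12) best <- list(gr = gr, feature = j, threshold = t)
      }
    }
  }
  best
}

# Sort-based mean-rank oracle (higher metric -> higher rank, k = best).
loop_mean_ranks <- function(tbl) {
  k <- nrow(tbl)
  ranks <- matrix(0, k, ncol(tbl))
  for (j in seq_len(ncol(tbl))) {
    ranks[, j] <- rank(tbl[, j], ties.method = "average")
  }
  rowMeans(ranks)
}

# Write a tabular_dataset-shaped CSV by hand (independent of write_dataset).
write_fixture_csv <- function(path, features, labels, label_col = "class") {
  df <- as.data.frame(features)
  df[[label_col]] <- labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# The bundled 12-dataset benchmark MCC table, methods in rows.
load_benchmark_mcc <- function() {
  f <- system.file("extdata", "benchmark_mcc.csv", package = "kboost")
  tbl <- utils::read.csv(f, row.names = 1L)
  t(as.matrix(tbl))
}
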