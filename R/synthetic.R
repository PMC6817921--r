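#' Generate a two-class imbalanced Gaussian-mixture dataset
#'
#' Produces a dataset with deterministic class counts: the minority
#' (positive) class has `round(n / (1 + ir))` rows and the majority the
#' remainder, so the realised imbalance ratio matches the request at the
#' count level.  Each class is a Gaussian mixture with unit within-component
#' standard deviation; the class mean vectors are `separation` apart along
#' the first feature axis, so `separation` is expressed in within-class
#' standard deviations.  With `n_subclusters > 1` each class is split evenly
#' over sub-blobs whose centres are jittered around the class mean.
#'
#' @param n Total rows (`>= 4`).
#' @param ir Target imbalance ratio (`>= 1`).
#' @param dims Number of features (`>= 1`).
#' @param separation Distance between the class means, in units of the
#'   within-class standard deviation; 0 means the classes are
#'   indistinguishable.
#' @param n_subclusters Sub-blobs per class (default 1).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A [tabular_dataset()] with labels `"neg"` / `"pos"`
#'   (positive = minority).
#' @export
#' @examples
#' ds <- make_imbalanced(n = 300, ir = 5, dims = 8, separation = 4, seed = 7)
#' class_counts(ds)      # 250 / 50
#' imbalance_ratio(ds)   # 5
make_imbalanced <- function(n = 600L, ir = 5, dims = 8L, separation = 4,
                            n_subclusters = 1L, seed = 1L) {
  stopifnot(n >= 4L, ir >= 1, dims >= 1L, separation >= 0, n_subclusters >= 1L)
  n_min <- round(n / (1 + ir))
  if (n_min < 2L) stop("minority count would be < 2; lower ir or raise n",
                       call. = FALSE)
  n_maj <- n - n_min
  mu_neg <- rep(0, dims)
  mu_pos <- c(separation, rep(0, dims - 1L))

  features <- withr::with_seed(seed, {
    rbind(.class_blob(n_maj, mu_neg, n_subclusters),
          .class_blob(n_min, mu_pos, n_subclusters))
  })
  colnames(features) <- paste0("x", seq_len(dims))
  labels <- c(rep("neg", n_maj), rep("pos", n_min))
  ds <- tabular_dataset(features, labels, positive = "pos")
  attr(ds, "spec") <- list(n = n, ir = ir, dims = dims,
                           separation = separation,
                           n_subclusters = n_subclusters, seed = seed)
  ds
}

# One class: n points split as evenly as possible over sub-blobs centred at
# mu + jitter, unit within-blob sd.  Consumes RNG; caller seeds.
.class_blob <- function(n, mu, n_subclusters) {
  dims <- length(mu)
  sizes <- diff(round(seq(0, n, length.out = n_subclusters + 1L)))
  centers <- matrix(stats::rnorm(n_subclusters * dims, sd = 1),
                    nrow = n_subclusters)
  if (n_subclusters == 1L) centers[] <- 0
  blocks <- lapply(seq_len(n_subclusters), function(b) {
    matrix(stats::rnorm(sizes[b] * dims), ncol = dims) +
      matrix(mu + centers[b, ], sizes[b], dims, byrow = TRUE)
  })
  do.call(rbind, blocks)
}

#' Small hand-checkable fixture datasets
#'
#' A named collection of tiny datasets with analytically known structure,
#' used across the package's tests and examples:
#' \describe{
#'   \item{`kmeans6`}{6 points in 2-D forming two tight triads; the optimal
#'     2-cluster partition is known by enumeration.}
#'   \item{`dist345`}{a point at (3, 4) with a centroid at the origin — its
#'     centroid distance is exactly 5.}
#'   \item{`stump`}{1-D, classes split exactly at x = 3 (points 1, 2, 4, 5).}
#'   \item{`xor`}{60 noisy XOR points — not linearly separable, so a depth-1
#'     tree cannot fit it but a boosted ensemble can.}
#'   \item{`quantile40`}{40 points on a ring with hand-placed centroid
#'     distances spanning known quantiles, for selection-threshold tests.}
#' }
#'
#' @param seed Integer seed; regeneration with the same seed is
#'   byte-identical.
#' @return Named list; each element holds a `features` matrix and `labels`,
#'   plus fixture-specific expectations.
#' @export
fixture_suite <- function(seed = 1L) {
  withr::with_seed(seed, {
    kmeans6 <- list(
      features = rbind(c(0, 0), c(0.5, 0), c(0, 0.5),
                       c(10, 10), c(10.5, 10), c(10, 10.5)),
      labels = rep(c("a", "b"), each = 3L),
      optimal_partition = rep(c(1L, 2L), each = 3L)
    )
    dist345 <- list(features = rbind(c(0, 0), c(3, 4)),
                    centroid = c(0, 0), expected_distance = 5)
    stump <- list(features = matrix(c(1, 2, 4, 5), ncol = 1L),
                  labels = c("a", "a", "b", "b"), threshold = 3)
    xor_n <- 60L
    xq <- sample(4L, xor_n, replace = TRUE)
    cx <- c(0, 0, 4, 4)[xq] + stats::rnorm(xor_n, sd = 0.6)
    cy <- c(0, 4, 0, 4)[xq] + stats::rnorm(xor_n, sd = 0.6)
    xor <- list(features = cbind(x = cx, y = cy),
                labels = ifelse(xq %in% c(1L, 4L), "a", "b"))
    ang <- seq(0, 2 * pi, length.out = 41L)[-41L]
    radii <- rep(c(0.5, 1, 2, 4), times = 10L)
    quantile40 <- list(
      features = cbind(radii * cos(ang), radii * sin(ang)),
      labels = rep(c("pos", "neg"), times = c(10L, 30L)),
      radii = radii
    )
    list(kmeans6 = kmeans6, dist345 = dist345, stump = stump, xor = xor,
         quantile40 = quantile40)
  })
}
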