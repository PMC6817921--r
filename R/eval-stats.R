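#' Two-class confusion matrix
#'
#' Counts with the convention that the positive class is the class of
#' interest (minority / case): `tp` true positives, `fn` false negatives,
#' `fp` false positives, `tn` true negatives.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param positive Positive label value; defaults to the second factor level
#'   of `y_true` (the package's positive-class slot).
#' @return An object of class `confusion_matrix` with integer elements
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- if (is.factor(y_true)) levels(y_true)[nlevels(y_true)] else
      sort(unique(as.character(y_true)))[length(unique(y_true))]
  }
  tp_mask <- as.character(y_true) == positive
  pp_mask <- as.character(y_pred) == positive
  structure(
    list(tp = sum(tp_mask & pp_mask), fn = sum(tp_mask & !pp_mask),
         fp = sum(!tp_mask & pp_mask), tn = sum(!tp_mask & !pp_mask),
         positive = positive),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fn=%d fp=%d tn=%d (positive='%s')\n",
              x$tp, x$fn, x$fp, x$tn, x$positive))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TN * TP - FN * FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' correlation-like summary in `[-1, 1]` that stays informative under class
#' imbalance.  When any marginal is zero the value is 0 by convention (the
#' predictions carry no information about the truth).
#'
#' @param cm A [confusion_matrix()], or a numeric vector/list with elements
#'   `tp`, `fn`, `fp`, `tn`.
#' @return A number in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  # counts promoted to double up front: the four-way product overflows the
  # integer range already at a few hundred evaluated rows
  tp <- as.numeric(cm$tp); fn <- as.numeric(cm$fn)
  fp <- as.numeric(cm$fp); tn <- as.numeric(cm$tn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tn * tp - fn * fp) / sqrt(denom)
}

#' Geometric mean of sensitivity and specificity
#'
#' @param sensitivity True-positive rate in `[0, 1]` (or percent; the result
#'   is then on the same percent scale when both arguments are).
#' @param specificity True-negative rate.
#' @return `sqrt(sensitivity * specificity)`.
#' @export
g_mean <- function(sensitivity, specificity) {
  sqrt(sensitivity * specificity)
}

#' Rank-based AUC of a score vector
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' ties handled by midranks (equivalent to the trapezoidal area under the
#' empirical ROC).
#'
#' @param y_true True labels.
#' @param scores Numeric scores, higher = more positive.
#' @param positive Positive label value (default: second factor level).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y_true, scores, positive = NULL) {
  if (is.null(positive)) {
    positive <- if (is.factor(y_true)) levels(y_true)[nlevels(y_true)] else
      sort(unique(as.character(y_true)))[length(unique(y_true))]
  }
  pos <- as.character(y_true) == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: one class is absent", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metric report from a confusion matrix
#'
#' Computes accuracy, sensitivity (recall of the positive class),
#' specificity, G-mean, AUC and MCC.  When `scores` are supplied the AUC is
#' the rank-based ROC area; otherwise it falls back to
#' `(sensitivity + specificity) / 2` and `auc_type` is flagged
#' `"balanced_accuracy_fallback"`.  If a class is absent from `y_true` the
#' corresponding rate (and G-mean) is `NA` rather than a silent zero.
#'
#' @param cm A [confusion_matrix()].
#' @param scores Optional numeric scores aligned with `y_true`.
#' @param y_true Labels matching `scores` (required with `scores`).
#' @return An object of class `metric_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `g_mean`, `auc`, `mcc`, `auc_type`, `n`.
#' @export
metric_report <- function(cm, scores = NULL, y_true = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  sens <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  spec <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_
  if (!is.null(scores)) {
    if (is.null(y_true)) stop("y_true required with scores", call. = FALSE)
    auc <- auc_score(y_true, scores, positive = cm$positive)
    auc_type <- "roc_rank"
  } else {
    auc <- (sens + spec) / 2
    auc_type <- "balanced_accuracy_fallback"
  }
  structure(
    list(accuracy = (cm$tp + cm$tn) / n, sensitivity = sens,
         specificity = spec, g_mean = g_mean(sens, spec), auc = auc,
         mcc = mcc(cm), auc_type = auc_type, n = n),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d acc=%.4f sens=%.4f spec=%.4f gmean=%.4f auc=%.4f mcc=%.4f\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$g_mean, x$auc, x$mcc))
  if (x$auc_type != "roc_rank") cat("  (AUC: ", x$auc_type, ")\n", sep = "")
  invisible(x)
}

#' Friedman mean ranks of methods across datasets
#'
#' Within each dataset (column) the methods are ranked by the metric, ties
#' receiving average ranks.  With `best = "k"` (default) the best method in a
#' column gets rank `k` (number of methods), so higher mean rank = better;
#' `best = "1"` flips to the convention where rank 1 is best.
#'
#' @param metric_table Numeric matrix, methods in rows, datasets in columns;
#'   higher metric = better.
#' @param best `"k"` or `"1"`.
#' @return Named numeric vector of per-method mean ranks.
#' @export
friedman_mean_ranks <- function(metric_table, best = c("k", "1")) {
  best <- match.arg(best)
  m <- as.matrix(metric_table)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 methods and 2 datasets", call. = FALSE)
  }
  if (anyNA(m)) stop("metric table has missing cells", call. = FALSE)
  ranks <- apply(m, 2L, rank)               # 1 = worst metric value
  if (best == "1") ranks <- nrow(m) + 1 - ranks
  mr <- rowMeans(ranks)
  names(mr) <- rownames(m)
  mr
}

#' Friedman rank test across datasets
#'
#' Tie-corrected Friedman chi-square statistic with `k - 1` degrees of
#' freedom, for `k` methods compared over `n` datasets (blocks); optionally
#' the Iman-Davenport F refinement.
#'
#' @param metric_table Numeric matrix, methods in rows, datasets in columns.
#' @param method `"chisq"` (default) or `"iman_davenport"`.
#' @return List with `statistic`, `p_value`, `df` (and `df2` for the F form).
#' @export
friedman_test <- function(metric_table, method = c("chisq", "iman_davenport")) {
  method <- match.arg(method)
  m <- as.matrix(metric_table)
  k <- nrow(m)
  n <- ncol(m)
  if (k < 2L || n < 2L) stop("need k >= 2 methods and n >= 2 datasets",
                             call. = FALSE)
  if (anyNA(m)) stop("metric table has missing cells", call. = FALSE)
  ranks <- apply(m, 2L, rank)
  Rj <- rowSums(ranks)
  # tie correction per block (dataset)
  tie_term <- sum(apply(ranks, 2L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  stat <- 12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  if (method == "chisq") {
    list(statistic = stat, p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
         df = k - 1L)
  } else {
    ff <- (n - 1) * stat / (n * (k - 1) - stat)
    list(statistic = ff,
         p_value = stats::pf(ff, k - 1, (k - 1) * (n - 1), lower.tail = FALSE),
         df = k - 1L, df2 = (k - 1L) * (n - 1L))
  }
}

#' Nemenyi critical difference
#'
#' Two methods differ significantly when their Friedman mean ranks differ by
#' more than `CD = q_alpha(k) * sqrt(k (k + 1) / (6 n))`, where `q_alpha` is
#' the Studentized-range quantile divided by `sqrt(2)`.
#'
#' @param k Number of methods (`>= 2`).
#' @param n Number of datasets (`>= 1`).
#' @param alpha Significance level (default 0.05).
#' @return The critical difference.
#' @export
#' @examples
#' nemenyi_cd(4, 10)  # ~1.483
nemenyi_cd <- function(k, n, alpha = 0.05) {
  stopifnot(k >= 2L, n >= 1L, alpha > 0, alpha < 1)
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * n))
}

#' Friedman/Nemenyi comparison of a methods-by-datasets metric table
#'
#' @param metric_table Numeric matrix, methods in rows, datasets in columns,
#'   higher = better.
#' @param alpha Significance level for the Nemenyi critical difference.
#' @param best Rank polarity passed to [friedman_mean_ranks()].
#' @return An object of class `rank_test_result`: `mean_ranks`,
#'   `friedman_statistic`, `p_value`, `nemenyi_cd`, `alpha`, and
#'   `significant` (logical k-by-k matrix of pairwise mean-rank differences
#'   exceeding the critical difference).
#' @export
rank_test <- function(metric_table, alpha = 0.05, best = c("k", "1")) {
  mr <- friedman_mean_ranks(metric_table, best = best)
  ft <- friedman_test(metric_table)
  cd <- nemenyi_cd(nrow(as.matrix(metric_table)),
                   ncol(as.matrix(metric_table)), alpha)
  diff <- abs(outer(mr, mr, "-"))
  structure(
    list(mean_ranks = mr, friedman_statistic = ft$statistic,
         p_value = ft$p_value, nemenyi_cd = cd, alpha = alpha,
         significant = diff > cd),
    class = "rank_test_result"
  )
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat("<rank_test_result>\n  mean ranks: ",
      paste(sprintf("%s=%.3f", names(x$mean_ranks), x$mean_ranks),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  Friedman chi-sq = %.4g, p = %.4g; Nemenyi CD(alpha=%.2f) = %.4g\n",
              x$friedman_statistic, x$p_value, x$alpha, x$nemenyi_cd))
  invisible(x)
}
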