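#' Per-dataset tuning defaults for the standard UCI benchmark suite
#'
#' The selection threshold `eta` and boosting-trial counts used for the
#' twelve UCI class-imbalance benchmark datasets this package's method was
#' tuned on.  The trial counts for the ten general-purpose datasets are
#' stored positionally against the published `eta` order; datasets not
#' listed here default to `eta = 1`, `trials = 10`.
#'
#' @return A data frame with columns `dataset`, `eta`, `trials`.
#' @export
benchmark_defaults <- function() {
  data.frame(
    dataset = c("Wbcd", "Bcwo", "Yeast1", "Redwine1", "Redwine4", "Abalone",
                "Yeast2", "Yeast3", "Redwine2", "Whitewine", "Pima",
                "Redwine3"),
    eta = c(0.25, 1, 0.5, 0.7, 0.8, 0.9, 1, 1, 1.2, 1.35, 1.5, 1.6),
    trials = c(10L, 10L, 10L, 3L, 8L, 4L, 3L, 1L, 7L, 1L, 3L, 8L),
    stringsAsFactors = FALSE
  )
}

#' Build an experiment configuration
#'
#' @param datasets Named list of [tabular_dataset()] objects, or of CSV paths
#'   (read with [read_dataset()] using `label_column`).
#' @param methods Character subset of `"kboost"`, `"adaboost"`, `"rusboost"`,
#'   `"smoteboost"`, `"smote_boosted"` (SMOTE once up front, then plain
#'   boosting).
#' @param eta Named numeric vector of per-dataset selection thresholds;
#'   unnamed scalar applies to all.  Default 1.
#' @param trials Named integer vector of per-dataset boosting rounds;
#'   unnamed scalar applies to all.  Default 10.
#' @param protocol `"cv10"` (stratified cross-validation with all resampling
#'   or selection fitted inside each training fold — the leakage-free
#'   protocol, default) or `"selection_holdout"` (train on the balanced
#'   selected subset, test on the rejected remainder; every method is
#'   evaluated on the same holdout rows).
#' @param k_folds Folds for `"cv10"` (default 10).
#' @param smote_p A [smote_params()] object for the SMOTE-based methods.
#' @param selection Template [selection_params()]; its `eta` and `seed` are
#'   overridden per dataset / run.
#' @param tree_params List of [fit_tree()] settings.
#' @param label_column Label column used when `datasets` entries are paths.
#' @param seed Integer master seed.
#' @param verbose Emit per-fold progress messages.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(datasets,
                              methods = c("kboost", "rusboost", "smoteboost",
                                          "smote_boosted"),
                              eta = 1, trials = 10L,
                              protocol = c("cv10", "selection_holdout"),
                              k_folds = 10L, smote_p = smote_params(),
                              selection = selection_params(),
                              tree_params = list(), label_column = "class",
                              seed = 1L, verbose = FALSE) {
  protocol <- match.arg(protocol)
  known <- c("kboost", "adaboost", "rusboost", "smoteboost", "smote_boosted")
  methods <- match.arg(methods, known, several.ok = TRUE)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    stop("datasets must be a fully named list", call. = FALSE)
  }
  datasets <- lapply(datasets, function(d) {
    if (inherits(d, "tabular_dataset")) d else
      read_dataset(d, label_column = label_column)
  })
  structure(
    list(datasets = datasets, methods = methods,
         eta = .per_dataset(eta, names(datasets), 1),
         trials = .per_dataset(trials, names(datasets), 10L),
         protocol = protocol, k_folds = as.integer(k_folds),
         smote_p = smote_p, selection = selection,
         tree_params = tree_params, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "experiment_config"
  )
}

.per_dataset <- function(x, ds_names, default) {
  out <- stats::setNames(rep(default, length(ds_names)), ds_names)
  if (is.null(names(x))) {
    if (length(x) == 1L) out[] <- x else {
      stopifnot(length(x) == length(ds_names))
      out[] <- x
    }
  } else {
    out[intersect(names(x), ds_names)] <- x[intersect(names(x), ds_names)]
  }
  out
}

#' Run a multi-dataset, multi-method comparison experiment
#'
#' Under `"cv10"`, each dataset is split into stratified folds; for every
#' fold, the rebalancing step (cluster-based selection, RUS, or SMOTE) and
#' the classifier are fitted on the training folds only, and predictions on
#' the held-out fold are pooled into one confusion matrix per
#' (dataset, method) pair (micro-averaging).  Under `"selection_holdout"`,
#' the cluster-based selection on the full dataset defines a single balanced
#' train / rejected test split shared by every method.
#'
#' @param config An [experiment_config()].
#' @return A data frame of class `results_table`, one row per
#'   (dataset, method), with the six metrics, the pooled confusion counts,
#'   and `n_evaluated`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (ds_name in names(config$datasets)) {
    ds <- config$datasets[[ds_name]]
    eta <- config$eta[[ds_name]]
    trials <- config$trials[[ds_name]]
    for (method in config$methods) {
      res <- tryCatch(
        .run_one(ds, method, eta, trials, config),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        warning("dataset '", ds_name, "', method '", method, "' failed: ",
                conditionMessage(res), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds_name, method = method, accuracy = NA_real_,
          sensitivity = NA_real_, specificity = NA_real_, g_mean = NA_real_,
          auc = NA_real_, mcc = NA_real_, tp = NA_integer_, fn = NA_integer_,
          fp = NA_integer_, tn = NA_integer_, n_evaluated = NA_integer_,
          failed = TRUE, stringsAsFactors = FALSE)
        next
      }
      rep <- metric_report(res$cm, scores = res$scores, y_true = res$y_true)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds_name, method = method, accuracy = rep$accuracy,
        sensitivity = rep$sensitivity, specificity = rep$specificity,
        g_mean = rep$g_mean, auc = rep$auc, mcc = rep$mcc,
        tp = res$cm$tp, fn = res$cm$fn, fp = res$cm$fp, tn = res$cm$tn,
        n_evaluated = rep$n, failed = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("results_table", class(out))
  out
}

# Evaluate one (dataset, method) cell; returns pooled confusion + scores.
.run_one <- function(ds, method, eta, trials, config) {
  if (config$protocol == "cv10") {
    folds <- stratified_kfold(ds, config$k_folds, seed = config$seed)
    y_true <- character(0L)
    y_pred <- character(0L)
    scores <- numeric(0L)
    for (f in seq_len(config$k_folds)) {
      test_idx <- which(folds$fold == f)
      train_idx <- which(folds$fold != f)
      fit_seed <- config$seed + 131L * f
      model <- .fit_method(subset_rows(ds, train_idx), method, eta, trials,
                           config, fit_seed)
      Xte <- ds$features[test_idx, , drop = FALSE]
      y_true <- c(y_true, as.character(ds$labels[test_idx]))
      y_pred <- c(y_pred, as.character(predict(model, Xte)))
      scores <- c(scores, predict(model, Xte, type = "score"))
      if (config$verbose) {
        message(sprintf("  fold %d/%d done (%s)", f, config$k_folds, method))
      }
    }
    cm <- confusion_matrix(y_true, y_pred, positive = ds$positive)
    list(cm = cm, scores = scores, y_true = y_true)
  } else {
    sel_par <- config$selection
    sel_par$eta <- eta
    sel_par$seed <- config$seed
    selection <- select_informative(ds, sel_par)
    split <- split_train_test(ds, selection)
    model <- .fit_method(split$train, method, eta, trials, config,
                         config$seed, preselected = TRUE)
    Xte <- split$test$features
    y_true <- as.character(split$test$labels)
    cm <- confusion_matrix(y_true, as.character(predict(model, Xte)),
                           positive = ds$positive)
    list(cm = cm, scores = predict(model, Xte, type = "score"),
         y_true = y_true)
  }
}

# Fit one method on a training dataset.  `preselected` marks that the
# cluster-based selection already produced this training set (holdout
# protocol), in which case "kboost" reduces to plain boosting.
.fit_method <- function(train, method, eta, trials, config, seed,
                        preselected = FALSE) {
  X <- train$features
  y <- train$labels
  switch(
    method,
    kboost = {
      if (preselected) {
        fit_adaboost(X, y, trials, config$tree_params, seed)
      } else {
        sel_par <- config$selection
        sel_par$eta <- eta
        sel_par$seed <- seed
        fit_k_boosted(train, kboost_params(sel_par, trials,
                                           config$tree_params, seed))
      }
    },
    adaboost = fit_adaboost(X, y, trials, config$tree_params, seed),
    rusboost = fit_rusboost(X, y, trials, config$tree_params, seed),
    smoteboost = {
      sp <- config$smote_p
      sp$seed <- seed
      fit_smoteboost(X, y, trials, sp, config$tree_params, seed)
    },
    smote_boosted = {
      sp <- config$smote_p
      sp$seed <- seed
      res <- smote(train, sp)
      fit_adaboost(res$features, res$labels, trials, config$tree_params, seed)
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Friedman/Nemenyi comparison from an experiment results table
#'
#' Pivots a [run_experiment()] table into a methods-by-datasets matrix for
#' the chosen metric and delegates to [rank_test()].
#'
#' @param results A `results_table` data frame.
#' @param metric Metric column to compare (default `"mcc"`).
#' @param alpha Significance level (default 0.05).
#' @param best Rank polarity (see [friedman_mean_ranks()]).
#' @return A [rank_test()] result.
#' @export
compare_methods <- function(results, metric = "mcc", alpha = 0.05,
                            best = c("k", "1")) {
  stopifnot(metric %in% names(results))
  methods <- unique(results$method)
  datasets <- unique(results$dataset)
  if (length(methods) < 2L) stop("need at least two methods", call. = FALSE)
  tbl <- matrix(NA_real_, length(methods), length(datasets),
                dimnames = list(methods, datasets))
  for (i in seq_len(nrow(results))) {
    tbl[results$method[i], results$dataset[i]] <- results[[metric]][i]
  }
  if (anyNA(tbl)) stop("incomplete results table for metric '", metric, "'",
                       call. = FALSE)
  rank_test(tbl, alpha = alpha, best = best)
}
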