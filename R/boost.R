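#' AdaBoost.M1 over gain-ratio decision trees
#'
#' Classical AdaBoost.M1 for two classes.  Case weights start uniform; each
#' trial fits a weighted [fit_tree()], computes the weighted training error
#' `eps_t`, stops when `eps_t >= 0.5` (tree discarded) and keeps the trial
#' with a capped vote weight when `eps_t = 0`; otherwise
#' `alpha_t = 0.5 * log((1 - eps_t) / eps_t)`, the weights are multiplied by
#' `exp(+/- alpha_t)` and renormalised.  Prediction is the alpha-weighted
#' vote; the score is the positive vote share `sum(alpha[h = +]) / sum(alpha)`
#' in `[0, 1]`.
#'
#' @param X Numeric feature matrix.
#' @param y Two-level factor (second level = positive class) or vector.
#' @param trials Maximum boosting rounds (default 10).
#' @param tree_params List of arguments for [fit_tree()] (`min_leaf`,
#'   `pruning_cf`).
#' @param seed Integer seed (only consumed by resampling variants; kept for a
#'   uniform interface).
#' @return An object of class `boosted_ensemble`: `trees`, `alphas`,
#'   `errors` (per-trial weighted error), `weight_history` (list of the
#'   normalised weight vector after each trial), `levels`, `trials`, `seed`.
#' @export
fit_adaboost <- function(X, y, trials = 10L, tree_params = list(), seed = 1L) {
  .boost(X, y, trials, tree_params, seed, resample = "none")
}

#' RUSBoost: AdaBoost.M1 with per-trial random undersampling
#'
#' Identical boosting loop to [fit_adaboost()], except that each weak learner
#' is fitted on a balanced subsample: all minority rows plus a majority
#' subset of the same size drawn without replacement with probability
#' proportional to the current boosting weights.  The weighted error and the
#' weight update are computed on the full training set.
#'
#' @inheritParams fit_adaboost
#' @export
fit_rusboost <- function(X, y, trials = 10L, tree_params = list(), seed = 1L) {
  .boost(X, y, trials, tree_params, seed, resample = "rus")
}

#' SMOTEBoost: AdaBoost.M1 with per-trial SMOTE augmentation
#'
#' Each weak learner is fitted on the training set augmented with SMOTE
#' synthetic minority rows (interpolated towards minority nearest
#' neighbours); synthetic rows receive the mean minority weight.  The
#' weighted error and the weight update are computed on the original rows
#' only.
#'
#' @inheritParams fit_adaboost
#' @param smote_p A [smote_params()] object (`over_pct` controls how many
#'   synthetic rows are added per trial; the majority class is not
#'   subsampled inside the boosting loop).
#' @export
fit_smoteboost <- function(X, y, trials = 10L, smote_p = smote_params(),
                           tree_params = list(), seed = 1L) {
  .boost(X, y, trials, tree_params, seed, resample = "smote", smote_p = smote_p)
}

# Shared boosting loop.  `resample` picks the per-trial weak-learner input.
.boost <- function(X, y, trials, tree_params, seed, resample,
                   smote_p = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("two classes required for boosting", call. = FALSE)
  if (trials < 1L) stop("trials must be >= 1", call. = FALSE)
  n <- nrow(X)
  w <- rep.int(1 / n, n)
  trees <- list()
  alphas <- numeric(0L)
  errors <- numeric(0L)
  weight_history <- list()
  trial_info <- list()
  alpha_cap <- 0.5 * log((1 - 1e-10) / 1e-10)

  for (t in seq_len(trials)) {
    trial_seed <- seed + 1000L * (t - 1L)
    fitted <- switch(
      resample,
      none = list(tree = do.call(fit_tree, c(list(X, y, sample_weights = w),
                                             tree_params)),
                  info = NULL),
      rus = .rus_trial(X, y, w, tree_params, trial_seed),
      smote = .smote_trial(X, y, w, tree_params, smote_p, trial_seed)
    )
    tree <- fitted$tree
    pred <- predict(tree, X)
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps >= 0.5) break  # weak-learner failure: discard and stop
    if (eps <= 0) {
      alpha <- alpha_cap
    } else {
      alpha <- 0.5 * log((1 - eps) / eps)
    }
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    errors <- c(errors, eps)
    trial_info[[length(trial_info) + 1L]] <- fitted$info
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
    weight_history[[length(weight_history) + 1L]] <- w
    if (eps <= 0) break  # perfect learner: keep it and stop
  }
  if (length(trees) == 0L) {
    # every trial failed: fall back to a single unweighted tree so the
    # ensemble still predicts (alpha 1, majority behaviour of the tree)
    trees <- list(do.call(fit_tree, c(list(X, y), tree_params)))
    alphas <- 1
    errors <- NA_real_
  }
  structure(
    list(trees = trees, alphas = alphas, errors = errors,
         weight_history = weight_history, trial_info = trial_info,
         levels = levels(y), trials = as.integer(trials),
         seed = as.integer(seed), resample = resample),
    class = "boosted_ensemble"
  )
}

# Balanced subsample for one RUSBoost trial: all minority rows plus an
# equal-size majority draw (probability proportional to boosting weight;
# plain uniform draw when the weights are still uniform, which makes a
# one-trial RUSBoost coincide with random_undersample + fit_tree).
.rus_trial <- function(X, y, w, tree_params, trial_seed) {
  cnt <- table(y)
  min_lv <- names(cnt)[which.min(cnt)]
  min_idx <- which(y == min_lv)
  maj_idx <- which(y != min_lv)
  keep <- withr::with_seed(trial_seed, {
    if (max(w) - min(w) < 1e-15) {
      sample(maj_idx, length(min_idx))
    } else {
      sample(maj_idx, length(min_idx), prob = w[maj_idx])
    }
  })
  sel <- sort(c(min_idx, keep))
  tree <- do.call(fit_tree, c(list(X[sel, , drop = FALSE], y[sel],
                                   sample_weights = w[sel]),
                              tree_params))
  list(tree = tree, info = list(rows = sel, class_counts = table(y[sel])))
}

# SMOTE-augmented training set for one SMOTEBoost trial.
.smote_trial <- function(X, y, w, tree_params, smote_p, trial_seed) {
  cnt <- table(y)
  min_lv <- names(cnt)[which.min(cnt)]
  min_idx <- which(y == min_lv)
  if (length(min_idx) <= smote_p$k_neighbors) {
    stop("minority count must exceed k_neighbors for SMOTEBoost", call. = FALSE)
  }
  Xmin <- X[min_idx, , drop = FALSE]
  n_copies <- smote_p$over_pct %/% 100L
  synth <- withr::with_seed(trial_seed, {
    nn <- .knn_indices(Xmin, smote_p$k_neighbors)
    .smote_synthesize(Xmin, nn, n_copies)
  })
  Xa <- rbind(X, synth)
  ya <- factor(c(as.character(y), rep(min_lv, nrow(synth))), levels = levels(y))
  wa <- c(w, rep(mean(w[min_idx]), nrow(synth)))
  tree <- do.call(fit_tree, c(list(Xa, ya, sample_weights = wa), tree_params))
  list(tree = tree, info = list(n_synth = nrow(synth)))
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  cat(sprintf("<boosted_ensemble> %s, %d tree(s) of %d trial(s), alpha in [%.3g, %.3g]\n",
              x$resample, length(x$trees), x$trials,
              min(x$alphas), max(x$alphas)))
  invisible(x)
}

#' Predict from a boosted ensemble
#'
#' @param object A fitted `boosted_ensemble`.
#' @param newdata Numeric feature matrix.
#' @param type `"class"` (default) or `"score"`.  The score is the
#'   alpha-weighted share of trees voting for the positive class, in
#'   `[0, 1]`; `"class"` thresholds the score at 0.5 with ties going to the
#'   negative class.
#' @param ... Unused.
#' @return Factor of labels or numeric score vector.
#' @export
predict.boosted_ensemble <- function(object, newdata,
                                     type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  votes <- vapply(object$trees, function(tr) {
    predict(tr, newdata) == object$levels[2L]
  }, logical(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  score <- as.vector(votes %*% object$alphas) / sum(object$alphas)
  if (type == "score") return(score)
  factor(ifelse(score > 0.5, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}

#' Parameters for the full undersample-then-boost pipeline
#'
#' @param selection A [selection_params()] object.
#' @param trials Boosting rounds (default 10).
#' @param tree_params List of [fit_tree()] settings.
#' @param seed Integer seed.
#' @return A list of class `kboost_params`.
#' @export
kboost_params <- function(selection = selection_params(), trials = 10L,
                          tree_params = list(), seed = 1L) {
  structure(list(selection = selection, trials = as.integer(trials),
                 tree_params = tree_params, seed = as.integer(seed)),
            class = "kboost_params")
}

#' Fit the cluster-undersampled boosted-tree pipeline
#'
#' Runs [select_informative()] on the dataset, trains [fit_adaboost()] on the
#' balanced selected subset, and keeps the selection result so the rejected
#' remainder can serve as a held-out test subset.
#'
#' @param ds A [tabular_dataset()].
#' @param params A [kboost_params()] object.
#' @return An object of class `kboost_model` with elements `ensemble`,
#'   `selection` and `params`; `predict()` delegates to the ensemble.
#' @export
#' @examples
#' ds <- make_imbalanced(n = 300, ir = 5, dims = 4, separation = 5, seed = 1)
#' fit <- fit_k_boosted(ds, kboost_params(selection_params(eta = 1, seed = 1)))
#' holdout <- subset_rows(ds, fit$selection$rejected_idx)
#' mean(predict(fit, holdout$features) == holdout$labels)
fit_k_boosted <- function(ds, params = kboost_params()) {
  stopifnot(inherits(ds, "tabular_dataset"), inherits(params, "kboost_params"))
  selection <- select_informative(ds, params$selection)
  train_idx <- selection$selected_idx
  ens <- fit_adaboost(ds$features[train_idx, , drop = FALSE],
                      ds$labels[train_idx], trials = params$trials,
                      tree_params = params$tree_params, seed = params$seed)
  structure(list(ensemble = ens, selection = selection, params = params,
                 levels = levels(ds$labels)),
            class = "kboost_model")
}

#' @export
print.kboost_model <- function(x, ...) {
  print(x$selection)
  print(x$ensemble)
  invisible(x)
}

#' @rdname fit_k_boosted
#' @param object A fitted `kboost_model`.
#' @param newdata Numeric feature matrix.
#' @param type `"class"` or `"score"`.
#' @param ... Unused.
#' @export
predict.kboost_model <- function(object, newdata,
                                 type = c("class", "score"), ...) {
  predict(object$ensemble, newdata, type = match.arg(type))
}
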