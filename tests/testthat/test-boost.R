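test_that("separable data with one trial gives a single perfect tree", {
  fx <- fixture_suite(seed = 1)
  ens <- fit_adaboost(fx$stump$features, fx$stump$labels, trials = 1)
  expect_length(ens$trees, 1L)
  expect_equal(as.character(predict(ens, fx$stump$features)), fx$stump$labels)
  # scores of a separable fit hit the extremes
  sc <- predict(ens, fx$stump$features, type = "score")
  expect_equal(sc, c(0, 0, 1, 1))
})

test_that("boosting invariants: weights normalised, accepted errors < 0.5", {
  fx <- fixture_suite(seed = 2)
  ens <- fit_adaboost(fx$xor$features, factor(fx$xor$labels), trials = 10,
                      tree_params = list(min_leaf = 5, pruning_cf = 0.25))
  for (w in ens$weight_history) {
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  expect_true(all(ens$errors < 0.5))
  expect_true(all(ens$alphas >= 0))
  expect_lte(length(ens$trees), 10L)
})

test_that("ensemble training error does not exceed the first tree's", {
  for (s in 1:5) {
    ds <- make_imbalanced(n = 150, ir = 2, dims = 3, separation = 1.5,
                          seed = s)
    ens <- fit_adaboost(ds$features, ds$labels, trials = 10, seed = s)
    first_err <- mean(predict(ens$trees[[1L]], ds$features) != ds$labels)
    ens_err <- mean(predict(ens, ds$features) != ds$labels)
    expect_lte(ens_err, first_err + 1e-12)
  }
})

test_that("boosted ensemble beats a depth-1 tree on noisy XOR", {
  fx <- fixture_suite(seed = 3)
  y <- factor(fx$xor$labels)
  stump_like <- fit_tree(fx$xor$features, y, min_leaf = 25, pruning_cf = NA)
  ens <- fit_adaboost(fx$xor$features, y, trials = 10,
                      tree_params = list(min_leaf = 5, pruning_cf = 0.25))
  err_stump <- mean(predict(stump_like, fx$xor$features) != y)
  err_ens <- mean(predict(ens, fx$xor$features) != y)
  expect_lte(err_ens, err_stump)
})

test_that("predict class equals thresholding the score at 0.5", {
  ds <- make_imbalanced(n = 200, ir = 3, dims = 3, separation = 2, seed = 4)
  ens <- fit_adaboost(ds$features, ds$labels, trials = 5, seed = 4)
  sc <- predict(ens, ds$features, type = "score")
  cls <- predict(ens, ds$features)
  expect_equal(as.character(cls), ifelse(sc > 0.5, "pos", "neg"))
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("RUSBoost trial-level training sets are exactly balanced", {
  ds <- make_imbalanced(n = 240, ir = 5, dims = 3, separation = 2, seed = 7)
  ens <- fit_rusboost(ds$features, ds$labels, trials = 5, seed = 7)
  for (info in ens$trial_info) {
    expect_equal(unname(info$class_counts[[1L]]),
                 unname(info$class_counts[[2L]]))
  }
})

test_that("one-trial RUSBoost equals RUS followed by a single tree", {
  ds <- make_imbalanced(n = 180, ir = 4, dims = 3, separation = 2, seed = 9)
  ens <- fit_rusboost(ds$features, ds$labels, trials = 1, seed = 11)
  rus <- random_undersample(ds, seed = 11)
  tree <- fit_tree(rus$features, rus$labels)
  Xg <- make_imbalanced(n = 100, ir = 4, dims = 3, separation = 2,
                        seed = 10)$features
  expect_equal(as.character(predict(ens, Xg)),
               as.character(predict(tree, Xg)))
})

test_that("SMOTEBoost recovers minority recall on skewed data", {
  ds <- make_imbalanced(n = 330, ir = 10, dims = 4, separation = 2, seed = 13)
  plain <- fit_adaboost(ds$features, ds$labels, trials = 10, seed = 13)
  sb <- fit_smoteboost(ds$features, ds$labels, trials = 10,
                       smote_p = smote_params(over_pct = 300), seed = 13)
  sens_of <- function(m) {
    cm <- confusion_matrix(ds$labels, predict(m, ds$features), positive = "pos")
    cm$tp / (cm$tp + cm$fn)
  }
  expect_gte(sens_of(sb), sens_of(plain))
})

test_that("the full pipeline is deterministic and collapses cleanly", {
  ds <- make_imbalanced(n = 300, ir = 5, dims = 4, separation = 5, seed = 21)
  par <- kboost_params(selection_params(eta = 1, seed = 2), trials = 10,
                       seed = 2)
  f1 <- fit_k_boosted(ds, par)
  f2 <- fit_k_boosted(ds, par)
  expect_identical(predict(f1, ds$features), predict(f2, ds$features))
  # eta -> 0 with balance = none trains on the full data = plain AdaBoost
  par0 <- kboost_params(selection_params(eta = 1e-12, balance = "none",
                                         seed = 2), trials = 5, seed = 2)
  f0 <- fit_k_boosted(ds, par0)
  plain <- fit_adaboost(ds$features, ds$labels, trials = 5, seed = 2)
  expect_equal(length(f0$selection$rejected_idx), 0L)
  expect_identical(predict(f0, ds$features), predict(plain, ds$features))
})
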