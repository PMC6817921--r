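blob_ds <- function(n_pos = 40, n_neg = 160, sep = 6, dims = 2, seed = 1) {
  make_imbalanced(n = n_pos + n_neg, ir = n_neg / n_pos, dims = dims,
                  separation = sep, seed = seed)
}

test_that("boundary rule keeps far-from-centroid points and enriches distance", {
  ds <- blob_ds(seed = 3)
  sel <- select_informative(ds, selection_params(eta = 1, balance = "none",
                                                seed = 1))
  d <- sel$distance
  thr <- sel$d_avg
  expect_true(all(d[sel$selected_idx] >= thr[sel$selected_idx]))
  expect_gt(mean(d[sel$selected_idx]), mean(d[sel$rejected_idx]))
})

test_that("threshold limits: eta near 0 selects all, huge eta errors", {
  ds <- blob_ds(seed = 5)
  sel <- select_informative(ds, selection_params(eta = 1e-9, balance = "none",
                                                seed = 1))
  expect_equal(length(sel$selected_idx), nrow(ds$features))
  expect_error(
    select_informative(ds, selection_params(eta = 1e6, balance = "none",
                                            seed = 1)),
    "degenerate selection")
})

test_that("selection equals an independent filter loop on a fixed clustering", {
  fx <- fixture_suite(seed = 1)
  ds <- tabular_dataset(fx$quantile40$features, fx$quantile40$labels,
                        positive = "pos")
  for (eta in c(0.4, 1, 1.7)) {
    for (rule in c("boundary", "interior")) {
      sel <- select_informative(ds, selection_params(eta = eta, K = 1,
                                                     rule = rule,
                                                     balance = "none",
                                                     seed = 1))
      oracle <- loop_select(sel$distance, sel$cluster, eta, rule)
      expect_equal(sel$selected_idx, oracle)
    }
  }
})

test_that("partition and eta-monotonicity properties hold over many seeds", {
  for (s in 1:50) {
    ds <- make_imbalanced(n = 120, ir = 3, dims = 3,
                          separation = runif(1, 0, 4), seed = s)
    p1 <- selection_params(eta = 0.6, balance = "none", seed = s)
    p2 <- selection_params(eta = 1.2, balance = "none", seed = s)
    s1 <- select_informative(ds, p1)
    s2 <- select_informative(ds, p2)
    # partition property
    expect_equal(sort(c(s1$selected_idx, s1$rejected_idx)), 1:120)
    expect_length(intersect(s1$selected_idx, s1$rejected_idx), 0)
    # monotone in eta under the boundary rule
    expect_true(all(s2$selected_idx %in% s1$selected_idx))
    # boundary enrichment
    expect_gte(mean(s1$distance[s1$selected_idx]),
               mean(s1$distance[s1$rejected_idx]))
  }
})

test_that("balancing yields exactly equal class counts", {
  for (s in 1:10) {
    ds <- make_imbalanced(n = 200, ir = 4, dims = 2, separation = 3, seed = s)
    sel <- select_informative(ds, selection_params(eta = 0.8, balance = "trim",
                                                   seed = s))
    cnt <- sel$per_class_selected
    expect_equal(unname(cnt[["positive"]]), unname(cnt[["negative"]]))
    expect_true(sel$balanced)
  }
})

test_that("pure trim drops the smallest-distance rows of the larger class", {
  fx <- fixture_suite(seed = 1)
  ds <- tabular_dataset(fx$quantile40$features, fx$quantile40$labels,
                        positive = "pos")
  # K=1 around the origin: distance = radius, known exactly
  sel <- select_informative(ds, selection_params(eta = 1e-9, K = 1,
                                                 balance = "none", seed = 1))
  expect_equal(length(sel$selected_idx), 40L)           # (10 pos, 30 neg)
  par <- selection_params(eta = 1e-9, K = 1, balance = "trim", seed = 1)
  bal <- rebalance(sel, ds, par)
  expect_equal(unname(bal$per_class_selected), c(10L, 10L))
  # the 10 retained negatives are those with the largest radii
  neg_idx <- which(!positive_mask(ds))
  kept_neg <- intersect(bal$selected_idx, neg_idx)
  top10 <- neg_idx[order(-sel$distance[neg_idx], neg_idx)][1:10]
  expect_setequal(kept_neg, top10)
  # an already balanced selection is a no-op
  bal2 <- rebalance(bal, ds, par)
  expect_identical(bal2$selected_idx, bal$selected_idx)
})

test_that("relax_eta halves the deficient class threshold then equalises", {
  # radial fixture with exact geometry: 10 pos at radius 4, 20 neg at 0.5,
  # 20 neg at 3.5, evenly spaced angles so the K=1 centroid is the origin
  # and every distance equals its radius; mean distance is exactly 2.4
  ring <- function(r, m) cbind(r * cos(2 * pi * (1:m) / m),
                               r * sin(2 * pi * (1:m) / m))
  feats <- rbind(ring(4, 10), ring(0.5, 20), ring(3.5, 20))
  ds <- tabular_dataset(feats, rep(c("pos", "neg"), times = c(10, 40)),
                        positive = "pos")
  sel <- select_informative(ds, selection_params(eta = 1.55, K = 1,
                                                 balance = "none", seed = 1))
  # threshold 1.55 * 2.4 = 3.72: only the radius-4 positives pass
  expect_equal(unname(sel$per_class_selected), c(0L, 10L))
  par <- selection_params(eta = 1.55, K = 1, balance = "relax_eta", seed = 1)
  bal <- rebalance(sel, ds, par)
  expect_equal(unname(bal$per_class_selected), c(10L, 10L))
  expect_equal(bal$eta_effective[["negative"]], 0.775)
  expect_equal(bal$eta_effective[["positive"]], 1.55)
  # the recruited negatives are the most informative (radius 3.5, not 0.5)
  neg_sel <- setdiff(bal$selected_idx, 1:10)
  expect_true(all(neg_sel > 30))
})

test_that("split_train_test partitions and rebalances the training side", {
  ds <- make_imbalanced(n = 300, ir = 5, dims = 3, separation = 4, seed = 2)
  sel <- select_informative(ds, selection_params(eta = 1, seed = 2))
  sp <- split_train_test(ds, sel)
  expect_equal(nrow(sp$train$features) + nrow(sp$test$features), 300L)
  expect_length(intersect(sel$selected_idx, sel$rejected_idx), 0)
  expect_equal(imbalance_ratio(sp$train), 1)
  expect_gt(imbalance_ratio(sp$test), 5)
  # concatenating both sides and sorting by original index reproduces ds
  all_idx <- c(sel$selected_idx, sel$rejected_idx)
  expect_equal(ds$features[sort(all_idx), ],
               rbind(sp$train$features, sp$test$features)[order(all_idx), ])
})

test_that("selection is idempotent at eta = 0 on its own output", {
  ds <- make_imbalanced(n = 200, ir = 3, dims = 2, separation = 3, seed = 6)
  sel <- select_informative(ds, selection_params(eta = 1, seed = 1))
  sub <- subset_rows(ds, sel$selected_idx)
  again <- select_informative(sub, selection_params(eta = 1e-12,
                                                    balance = "none",
                                                    seed = 1))
  expect_equal(again$selected_idx, seq_len(nrow(sub$features)))
})
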