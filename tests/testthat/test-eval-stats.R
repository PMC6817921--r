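test_that("confusion matrix counts match a direct loop", {
  cm <- confusion_matrix(rep(c("pos", "neg"), each = 10),
                         rep(c("pos", "neg"), each = 10), positive = "pos")
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(10L, 0L, 0L, 10L))

  set.seed(1)
  yt <- sample(c("pos", "neg"), 50, replace = TRUE)
  yp <- sample(c("pos", "neg"), 50, replace = TRUE)
  cm2 <- confusion_matrix(yt, yp, positive = "pos")
  expect_equal(cm2$tp, sum(yt == "pos" & yp == "pos"))
  expect_equal(cm2$fn, sum(yt == "pos" & yp == "neg"))
  expect_equal(cm2$fp, sum(yt == "neg" & yp == "pos"))
  expect_equal(cm2$tn, sum(yt == "neg" & yp == "neg"))
  # flipping all predictions swaps tp<->fn and tn<->fp
  flip <- ifelse(yp == "pos", "neg", "pos")
  cmf <- confusion_matrix(yt, flip, positive = "pos")
  expect_equal(c(cmf$tp, cmf$fn, cmf$fp, cmf$tn),
               c(cm2$fn, cm2$tp, cm2$tn, cm2$fp))
  expect_error(confusion_matrix(yt, yp[-1]), "lengths differ")
})

test_that("MCC conventions: perfect 1, inverted -1, independent 0", {
  mk <- function(tp, fn, fp, tn) list(tp = tp, fn = fn, fp = fp, tn = tn)
  expect_equal(mcc(mk(10, 0, 0, 10)), 1)
  expect_equal(mcc(mk(0, 10, 10, 0)), -1)
  expect_equal(mcc(mk(15, 1, 0, 16)), (16 * 15 - 1 * 0) / sqrt(15 * 16 * 16 * 17))
  expect_equal(round(mcc(mk(15, 1, 0, 16)), 4), 0.9393)
  # zero marginals (e.g. constant predictor) return 0 by convention
  expect_equal(mcc(mk(0, 0, 5, 5)), 0)    # no actual positives
  expect_equal(mcc(mk(5, 5, 0, 0)), 0)    # no actual negatives
  expect_equal(mcc(mk(0, 5, 0, 5)), 0)    # never predicts positive
  # class-relabelling symmetry: swap tp<->tn and fp<->fn together
  expect_equal(mcc(mk(13, 4, 2, 31)), mcc(mk(31, 2, 4, 13)))
  # counts large enough that the marginal product exceeds integer range
  big <- mk(400L, 100L, 120L, 1380L)
  denom <- prod(c(400 + 120, 400 + 100, 1380 + 120, 1380 + 100))
  expect_equal(mcc(big), (1380 * 400 - 100 * 120) / sqrt(denom))
})

test_that("G-mean identity holds on published-style operating points", {
  expect_equal(round(g_mean(0.9375, 1), 4), 0.9682)
  expect_equal(round(g_mean(0.991, 0.969), 4), 0.9799)
  expect_equal(round(g_mean(100, 96.17), 2), 98.07)  # percent scale
  expect_equal(round(g_mean(0.957, 0.949), 3), 0.953)
})

test_that("metric report is internally consistent and flags degeneracy", {
  set.seed(3)
  yt <- factor(rep(c("neg", "pos"), times = c(30, 20)),
               levels = c("neg", "pos"))
  sc <- ifelse(yt == "pos", 1, 0) * 0.6 + runif(50) * 0.4
  yp <- ifelse(sc > 0.5, "pos", "neg")
  rep_ <- metric_report(confusion_matrix(yt, yp), scores = sc, y_true = yt)
  expect_equal(rep_$g_mean^2, rep_$sensitivity * rep_$specificity,
               tolerance = 1e-12)
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
  # perfectly ranked scores give AUC 1
  expect_equal(auc_score(yt, as.numeric(yt == "pos")), 1)
  # one class absent -> NA rates, not silent zeros
  cm1 <- confusion_matrix(rep("pos", 5), rep("pos", 5), positive = "pos")
  rep1 <- metric_report(cm1)
  expect_true(is.na(rep1$specificity))
  expect_true(is.na(rep1$g_mean))
  # without scores the AUC falls back to balanced accuracy and says so
  rep2 <- metric_report(confusion_matrix(yt, yp))
  expect_equal(rep2$auc, (rep2$sensitivity + rep2$specificity) / 2)
  expect_equal(rep2$auc_type, "balanced_accuracy_fallback")
})

test_that("AUC of permuted scores concentrates near one half", {
  set.seed(7)
  yt <- rep(c("neg", "pos"), times = c(60, 40))
  aucs <- replicate(1000, auc_score(yt, sample(runif(100))))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # and agrees with an independent ROC implementation when available
  skip_if_not_installed("pROC")
  sc <- runif(100)
  ref <- as.numeric(pROC::auc(pROC::roc(yt, sc, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc_score(yt, sc, positive = "pos"), ref, tolerance = 1e-12)
})

test_that("mean ranks: polarity, tie averaging, and sort-based oracle", {
  tbl <- rbind(a = c(3, 2, 5), b = c(3, 1, 4))
  mr <- friedman_mean_ranks(tbl)
  expect_equal(unname(mr), c((1.5 + 2 + 2) / 3, (1.5 + 1 + 1) / 3))
  # two methods with identical columns both get 1.5
  same <- rbind(a = c(1, 2), b = c(1, 2))
  expect_equal(unname(friedman_mean_ranks(same)), c(1.5, 1.5))
  # mean ranks always average to (k+1)/2
  set.seed(9)
  for (r in 1:10) {
    t2 <- matrix(runif(15), 3, 5)
    mr2 <- friedman_mean_ranks(t2)
    expect_equal(mean(mr2), 2)
    expect_equal(unname(mr2), loop_mean_ranks(t2))
    # Demsar polarity flips around the midpoint
    expect_equal(unname(friedman_mean_ranks(t2, best = "1")),
                 unname(4 - mr2))
  }
})

test_that("Friedman statistic matches closed forms and stats::friedman.test", {
  # identical methods: statistic 0, p 1 (ties -> 0/0 guarded by correction)
  one_best <- rbind(a = 2:11, b = 1:10)  # a strictly best everywhere, k=2
  ft <- friedman_test(one_best)
  expect_equal(ft$statistic, 12 * 10 / (2 * 3) * (0.5^2 + 0.5^2))
  expect_equal(ft$statistic, 10)
  set.seed(13)
  tbl <- matrix(runif(40), 4, 10)
  ft2 <- friedman_test(tbl)
  ref <- stats::friedman.test(t(tbl))
  expect_equal(ft2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ft2$p_value, ref$p.value, tolerance = 1e-10)
  # Iman-Davenport refinement has the documented F form
  ftid <- friedman_test(tbl, method = "iman_davenport")
  expect_equal(ftid$statistic,
               (10 - 1) * ft2$statistic / (10 * 3 - ft2$statistic))
})

test_that("Nemenyi critical difference matches the tabulated q values", {
  expect_equal(nemenyi_cd(4, 10, 0.05), 2.569 * sqrt(20 / 60), tolerance = 1e-3)
  expect_equal(nemenyi_cd(2, 10, 0.05), 1.960 * sqrt(6 / 60), tolerance = 1e-3)
  # monotone decreasing in n
  expect_gt(nemenyi_cd(4, 10), nemenyi_cd(4, 100))
  expect_lt(nemenyi_cd(4, 1e8), 1e-3)
})

test_that("rank_test composes ranks, test and CD with a dominance table", {
  tbl <- rbind(A = c(5, 5, 5, 5, 5), B = c(3, 3, 3, 3, 3),
               C = c(1, 1, 1, 1, 1))
  rt <- rank_test(tbl)
  expect_equal(unname(rt$mean_ranks), c(3, 2, 1))
  expect_equal(rt$nemenyi_cd, nemenyi_cd(3, 5))
  expect_true(rt$significant["A", "C"])
  expect_false(rt$significant["A", "B"])
})
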