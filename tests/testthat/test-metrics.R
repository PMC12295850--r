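test_that("confusion matrices equal brute-force pair counting", {
  classes <- c("a", "b", "c")
  for (s in 1:5) {
    set.seed(50 + s)
    truth <- sample(classes, 40, replace = TRUE)
    pred <- sample(classes, 40, replace = TRUE)
    cm <- confusion_matrix(truth, pred, classes)
    for (i in seq_along(classes)) for (j in seq_along(classes))
      expect_equal(cm[i, j], sum(truth == classes[i] & pred == classes[j]))
    expect_equal(sum(cm), 40L)
  }
  expect_error(confusion_matrix(c("a", "b"), c("a")), "length")
  expect_error(confusion_matrix(c("a", "x"), c("a", "a"), classes), "x")
  # perfect prediction is diagonal
  expect_equal(sum(confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))) -
                 sum(diag(confusion_matrix(c("a", "b", "c"), c("a", "b", "c")))),
               0L)
})

test_that("one-vs-rest counts conserve totals", {
  tabs <- published_tables()
  for (tb in tabs) {
    counts <- one_vs_rest_counts(tb$cm)
    expect_equal(counts$TP, tb$counts$TP)
    expect_equal(counts$TN, tb$counts$TN)
    expect_equal(counts$FP, tb$counts$FP)
    expect_equal(counts$FN, tb$counts$FN)
    expect_equal(sum(counts$TP), sum(diag(tb$cm)))
    expect_equal(unique(counts$TP + counts$TN + counts$FP + counts$FN),
                 sum(tb$cm))
  }
  # a diagonal matrix has no false calls
  d <- confusion_matrix(c("a", "b", "b"), c("a", "b", "b"))
  expect_equal(one_vs_rest_counts(d)$FP, c(0L, 0L))
  expect_equal(one_vs_rest_counts(d)$FN, c(0L, 0L))
})

test_that("published one-vs-rest counts reproduce the printed metric cells", {
  tb <- published_tables()$collected
  rows <- class_metrics(tb$counts)
  expect_equal(rhu(rows$precision), c(100, 100, 99.13))
  expect_equal(rhu(rows$recall), c(100, 99.12, 100))
  expect_equal(rhu(rows$f1), c(100, 99.56, 99.57))
  expect_equal(rhu(rows$accuracy), c(100, 99.76, 99.76))
  rep3 <- macro_and_overall(rows, tb$cm)
  expect_equal(rhu(rep3$macro), c(precision = 99.71, recall = 99.71, f1 = 99.71))
  expect_equal(rhu(rep3$overall_accuracy), 99.76)
})

test_that("degenerate denominators yield zero with a flag", {
  # class a: never truly present (TP + FN = 0) and never correct -> its
  # recall denominator is zero; precision is 0 by the convention
  counts <- data.frame(class = c("a", "b"), TP = c(0L, 5L), TN = c(0L, 3L),
                       FP = c(3L, 0L), FN = c(0L, 0L))
  rows <- class_metrics(counts)
  expect_equal(rows$precision[1], 0)
  expect_true(rows$degenerate[1])
  expect_false(rows$degenerate[2])
  # flagged rows are excluded from macro means
  rep <- macro_and_overall(rows, matrix(c(0, 5, 3, 0), 2,
                                        dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(unname(rep$macro["precision"]), 100)
  # single class, all correct
  one <- metrics_report(rep("a", 4), rep("a", 4))
  expect_equal(unname(one$macro), c(100, 100, 100))
  expect_equal(one$overall_accuracy, 100)
})

test_that("metrics are invariant to sample order and class order", {
  set.seed(61)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(c("a", "b", "c"), 60, TRUE))
  r1 <- metrics_report(truth, pred, c("a", "b", "c"))
  perm <- sample(60)
  r2 <- metrics_report(truth[perm], pred[perm], c("a", "b", "c"))
  expect_equal(r1$per_class, r2$per_class)
  r3 <- metrics_report(truth, pred, c("c", "a", "b"))
  expect_equal(sort(r3$macro), sort(r1$macro))
  expect_equal(r3$overall_accuracy, r1$overall_accuracy)
})

test_that("trapezoid ROC AUC matches the concordant-pair oracle", {
  # perfectly separated and perfectly inverted scores
  lab <- rep(c("pos", "neg"), each = 5)
  expect_equal(roc_curve_ovr(c(6:10, 1:5) / 10, lab, "pos")$auc, 1)
  expect_equal(roc_curve_ovr(c(1:5, 6:10) / 10, lab, "pos")$auc, 0)

  # tied and random scores against the O(n^2) oracle
  for (s in 1:5) {
    set.seed(70 + s)
    scores <- sample(seq(0, 1, by = 0.25), 20, replace = TRUE)
    pos <- runif(20) < 0.4
    if (!any(pos) || all(pos)) pos[1:2] <- c(TRUE, FALSE)
    roc <- roc_curve_ovr(scores, ifelse(pos, "p", "n"), "p")
    expect_equal(roc$auc, oracle_auc(scores, pos), tolerance = 1e-12)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[length(roc$fpr)], 1)
    expect_equal(roc$tpr[length(roc$tpr)], 1)
    expect_true(roc$auc >= 0 && roc$auc <= 1)
  }

  # agreement with an independent implementation
  set.seed(76)
  sc <- runif(50)
  lb <- ifelse(runif(50) < 0.5, "p", "n")
  expect_equal(roc_curve_ovr(sc, lb, "p")$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("n", "p"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-10)

  # label-independent scores hover at 0.5
  set.seed(77)
  expect_equal(roc_curve_ovr(runif(500), sample(c("p", "n"), 500, TRUE), "p")$auc,
               0.5, tolerance = 0.05)

  # one-class degeneracy is flagged
  expect_warning(r <- roc_curve_ovr(runif(5), rep("p", 5), "p"), "undefined")
  expect_true(r$degenerate)
  expect_true(is.na(r$auc))
})

test_that("display rounding is half-up at two decimals", {
  expect_equal(rhu(100 * 4478 / 4480), 99.96)   # 99.9553... -> 99.96
  expect_equal(rhu(99.125), 99.13)              # exact .5 rounds away from 0
  expect_equal(rhu(0.5, 0), 1)
  expect_equal(rhu(1.5, 0), 2)
  expect_equal(rhu(-0.5, 0), -1)
})
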