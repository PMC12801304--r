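test_that("confusion counts follow the 2x2 enumeration", {
  expect_equal(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1)),
               c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  y <- c(1, 0, 1, 1, 0)
  expect_equal(unname(confusionCounts(y, y)[c("FP", "FN")]), c(0L, 0L))
  # tally oracle on 500 random pairs
  set.seed(12)
  yt <- sample(0:1, 500, replace = TRUE)
  yp <- sample(0:1, 500, replace = TRUE)
  tab <- table(factor(yt, 0:1), factor(yp, 0:1))
  cm <- confusionCounts(yt, yp)
  expect_equal(unname(cm["TP"]), unname(tab["1", "1"]))
  expect_equal(unname(cm["TN"]), unname(tab["0", "0"]))
  expect_equal(unname(cm["FP"]), unname(tab["0", "1"]))
  expect_equal(unname(cm["FN"]), unname(tab["1", "0"]))
  expect_error(confusionCounts(c(1, 0), c(1)), "equal length")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
})

test_that("the closed-form metrics reproduce hand-computed values", {
  perfect <- computeMetrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("sensitivity", "specificity", "accuracy",
                                "precision", "f1", "mcc")]),
               rep(1, 6))
  coin <- computeMetrics(c(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(unname(coin["accuracy"]), 0.5)
  expect_equal(unname(coin["mcc"]), 0)
  expect_equal(unname(coin["f1"]), 0.5)
  # direct substitution on an asymmetric matrix
  m <- computeMetrics(c(TP = 30, TN = 40, FP = 10, FN = 20))
  expect_equal(unname(m["sensitivity"]), 30 / 50)
  expect_equal(unname(m["specificity"]), 40 / 50)
  expect_equal(unname(m["accuracy"]), 70 / 100)
  expect_equal(unname(m["precision"]), 30 / 40)
  expect_equal(unname(m["f1"]),
               2 * (30 / 40) * (30 / 50) / ((30 / 40) + (30 / 50)))
  expect_equal(unname(m["mcc"]),
               (30 * 40 - 10 * 20) / sqrt(40 * 50 * 50 * 60))
})

test_that("degenerate confusion cells report 0 with a warning", {
  warns <- capture_warnings(
    m <- computeMetrics(c(TP = 0, TN = 5, FP = 0, FN = 0)))
  expect_match(warns, "undefined", all = TRUE)
  expect_true(any(grepl("sensitivity", warns)))
  expect_equal(unname(m["sensitivity"]), 0)
  expect_equal(unname(m["mcc"]), 0)
})

test_that("label swap exchanges sensitivity/specificity and negates MCC", {
  set.seed(14)
  yt <- sample(0:1, 200, replace = TRUE)
  yp <- sample(0:1, 200, replace = TRUE)
  a <- suppressWarnings(computeMetrics(confusionCounts(yt, yp)))
  b <- suppressWarnings(computeMetrics(confusionCounts(1 - yt, 1 - yp)))
  expect_equal(unname(a["sensitivity"]), unname(b["specificity"]))
  expect_equal(unname(a["specificity"]), unname(b["sensitivity"]))
  swapPred <- suppressWarnings(computeMetrics(confusionCounts(yt, 1 - yp)))
  expect_equal(unname(swapPred["mcc"]), -unname(a["mcc"]))
})

test_that("AUC limits, pairwise oracle and invariance hold", {
  y <- c(1, 1, 0, 0)
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), y), 1)
  expect_equal(aucScore(c(0.1, 0.2, 0.8, 0.9), y), 0)
  expect_equal(aucScore(rep(0.5, 4), y), 0.5)
  set.seed(15)
  s <- round(rnorm(200), 1)  # rounding forces ties
  yt <- sample(0:1, 200, replace = TRUE)
  pos <- s[yt == 1]; neg <- s[yt == 0]
  brute <- mean(outer(pos, neg, function(p, n)
    (p > n) + 0.5 * (p == n)))
  expect_equal(aucScore(s, yt), brute, tolerance = 1e-12)
  # invariant under strictly increasing transforms
  expect_equal(aucScore(exp(3 * s), yt), aucScore(s, yt))
})

test_that("ROC curve is monotone with trapezoid area equal to rank AUC", {
  expect_equal(rocCurve(c(0.9, 0.1), c(1, 0))[, c("fpr", "tpr")],
               data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)),
               ignore_attr = TRUE)
  set.seed(16)
  s <- round(rnorm(200), 1)
  yt <- sample(0:1, 200, replace = TRUE)
  roc <- rocCurve(s, yt)
  expect_false(is.unsorted(roc$fpr))
  expect_false(is.unsorted(roc$tpr))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(attr(roc, "auc"), aucScore(s, yt), tolerance = 1e-9)
  expect_error(rocCurve(s, rep(1, 200)), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  s <- rnorm(150)
  yt <- sample(0:1, 150, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(yt, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(aucScore(s, yt), ref, tolerance = 1e-12)
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(18)
  for (i in 1:20) {
    cm <- confusionCounts(sample(0:1, 50, replace = TRUE),
                          sample(0:1, 50, replace = TRUE))
    m <- suppressWarnings(computeMetrics(cm))
    p <- m[["precision"]]; r <- m[["sensitivity"]]
    if (p + r > 0)
      expect_equal(m[["f1"]], 2 * p * r / (p + r), tolerance = 1e-12)
  }
})
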