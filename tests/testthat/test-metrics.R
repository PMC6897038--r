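test_that("confusion counts follow the published layout", {
  truth <- rep(c("nodule", "nonnodule"), c(5, 3))
  cc <- confusionCounts(truth, truth)
  expect_equal(c(cc@tp, cc@fp, cc@fn, cc@tn), c(5L, 0L, 0L, 3L))
  flipped <- ifelse(truth == "nodule", "nonnodule", "nodule")
  cf <- confusionCounts(truth, flipped)
  expect_equal(c(cf@tp, cf@fp, cf@fn, cf@tn), c(0L, 5L, 3L, 0L))
  expect_error(confusionCounts(truth, rep("lesion", 8)), "unknown label")
  expect_error(confusionCounts(truth, truth[-1]), "equal length")
})

test_that("counts match a direct tally loop on random labels", {
  set.seed(33)
  lv <- c("nodule", "nonnodule")
  truth <- sample(lv, 50, replace = TRUE)
  pred <- sample(lv, 50, replace = TRUE)
  cc <- confusionCounts(truth, pred)
  tally <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in 1:50) {
    if (truth[i] == "nodule") {
      if (pred[i] == "nodule") tally["tp"] <- tally["tp"] + 1
      else tally["fp"] <- tally["fp"] + 1
    } else {
      if (pred[i] == "nodule") tally["fn"] <- tally["fn"] + 1
      else tally["tn"] <- tally["tn"] + 1
    }
  }
  expect_equal(c(cc@tp, cc@fp, cc@fn, cc@tn), unname(tally))
  # row sums recover the class totals (the layout invariant)
  expect_equal(cc@tp + cc@fp, sum(truth == "nodule"))
  expect_equal(cc@fn + cc@tn, sum(truth == "nonnodule"))
})

test_that("the panel reproduces the published reference values", {
  p <- metricsPanel(confusionFromCounts(452, 15, 13, 118))
  expect_equal(p$accuracy, 95.32, tolerance = 0.005)
  expect_equal(p$fscore, 97.0, tolerance = 0.02)
  expect_equal(metricsPanel(confusionFromCounts(430, 37, 27, 104))$ppv,
               92.0, tolerance = 0.1)
  expect_equal(metricsPanel(confusionFromCounts(453, 14, 15, 116))$kappa,
               85.78, tolerance = 0.02)
})

test_that("a perfect matrix scores 100 on every metric", {
  p <- metricsPanel(confusionFromCounts(10, 0, 0, 5))
  for (m in c("accuracy", "sensitivity", "specificity", "kappa", "precision",
              "recall", "fscore", "ppv", "npv"))
    expect_equal(p[[m]], 100)
  expect_length(attr(p, "flags"), 0L)
})

test_that("zero denominators are reported as 0 and flagged", {
  p <- metricsPanel(confusionFromCounts(0, 0, 3, 5))
  expect_equal(p$sensitivity, 0)
  expect_equal(p$fscore, 0)
  expect_true(all(c("sensitivity", "fscore") %in% attr(p, "flags")))
})

test_that("accuracy is label-convention invariant and kappa is rater-symmetric", {
  set.seed(34)
  for (rep in 1:5) {
    truth <- sample(c("nodule", "nonnodule"), 40, replace = TRUE)
    pred <- sample(c("nodule", "nonnodule"), 40, replace = TRUE)
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    p1 <- metricsPanel(confusionCounts(truth, pred))
    swap <- function(x) ifelse(x == "nodule", "nonnodule", "nodule")
    p2 <- metricsPanel(confusionCounts(swap(truth), swap(pred)))
    expect_equal(p1$accuracy, p2$accuracy)
    p3 <- metricsPanel(confusionCounts(pred, truth))
    expect_equal(p1$kappa, p3$kappa, tolerance = 1e-9)
    # kappa from the marginal formula equals the direct label-vector tally
    expect_equal(p1$kappa, 100 * oracleKappa(truth, pred), tolerance = 1e-9)
    # F lies between precision and recall when both are positive
    if (p1$precision > 0 && p1$recall > 0) {
      expect_gte(p1$fscore, min(p1$precision, p1$recall) - 1e-9)
      expect_lte(p1$fscore, max(p1$precision, p1$recall) + 1e-9)
    }
  }
})

test_that("every reproducible published value matches its recomputation", {
  v <- verifyPrintedMetrics()
  known_bad <- (v$metric == "specificity") |
    (v$combo == "SVM_CNN" & v$metric == "fscore") |
    (v$combo == "RF_HOG" & v$metric == "kappa")
  expect_true(all(v$match[!known_bad]))
  # the four published values that do not follow from their own matrices
  expect_true(all(!v$match[known_bad]))
  expect_equal(nrow(v), 28L)
})

test_that("printed confusion matrices have the expected class totals", {
  pc <- printedConfusions()
  expect_equal(nrow(pc), 36L)
  ok <- pc$tp + pc$fp == 467L & pc$fn + pc$tn == 131L
  # one printed row (KNN HOG+CNN) sums to 457 nodules; all others check out
  expect_equal(pc$combo[!ok], "KNN_HOG_CNN")
})
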