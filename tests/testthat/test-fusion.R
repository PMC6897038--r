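# small feature table shared by the grid tests
makeFeatureSE <- function(n = 40, seed = 17) {
  set.seed(seed)
  lab <- rep(c("nodule", "nonnodule"), length.out = n)
  blocks <- list()
  for (d in names(descriptorLengths())) {
    len <- descriptorLengths()[[d]]
    m <- matrix(rnorm(len * n, sd = 0.2), len, n)
    # class signal in the first feature of each block
    m[1, ] <- m[1, ] + ifelse(lab == "nodule", 2, -2)
    rownames(m) <- sprintf("%s_f%04d", d, seq_len(len) - 1L)
    blocks[[d]] <- m
  }
  feat <- do.call(rbind, blocks)
  colnames(feat) <- sprintf("sample%04d", seq_len(n))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    rowData = S4Vectors::DataFrame(
      descriptor = rep(names(blocks), vapply(blocks, nrow, 0L)),
      row.names = rownames(feat)),
    colData = S4Vectors::DataFrame(label = lab,
                                   row.names = colnames(feat)))
}

test_that("fusion concatenates descriptors in canonical order with additive lengths", {
  se <- makeFeatureSE(6)
  one <- fuseFeatures(se, "HOG")
  expect_equal(nrow(one), 1296L)
  expect_equal(unname(one),
               unname(SummarizedExperiment::assay(se)[1:1296, ]))
  two <- fuseFeatures(se, c("CNN", "HOG"))  # canonical order puts HOG first
  expect_equal(nrow(two), 1336L)
  expect_equal(unname(two[1:1296, ]), unname(one))
  three <- fuseFeatures(se, c("ExHOG", "CNN", "LBP"))
  expect_equal(nrow(three), 648L + 40L + 256L)
  expect_equal(unname(three[1:648, ]),
               unname(fuseFeatures(se, "ExHOG")))
  # list form mirrors the matrix form
  lst <- list(HOG = rnorm(5), CNN = rnorm(3))
  expect_equal(fuseFeatures(lst, c("CNN", "HOG")), c(lst$HOG, lst$CNN),
               ignore_attr = TRUE)
  expect_error(fuseFeatures(se, character()), "non-empty")
  expect_error(fuseFeatures(list(HOG = 1), c("HOG", "CNN")), "missing")
  expect_error(fuseFeatures(se, "SIFT"), "unknown")
})

test_that("1-NN reproduces its own training labels on distinct points", {
  set.seed(23)
  x <- matrix(rnorm(60), 20, 3)
  y <- factor(rep(c("nodule", "nonnodule"), 10), c("nodule", "nonnodule"))
  m <- trainClassifier(x, y, "KNN")
  expect_equal(mean(predictClassifier(m, x) == y), 1.0)
})

test_that("SVM separates linearly separable blobs perfectly", {
  set.seed(24)
  xtr <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
  ytr <- factor(rep(c("nodule", "nonnodule"), each = 20), c("nodule", "nonnodule"))
  xte <- rbind(matrix(rnorm(20, 3), 10, 2), matrix(rnorm(20, -3), 10, 2))
  yte <- factor(rep(c("nodule", "nonnodule"), each = 10), c("nodule", "nonnodule"))
  m <- trainClassifier(xtr, ytr, "SVM")
  expect_equal(mean(predictClassifier(m, xte) == yte), 1.0)
})

test_that("random forest predictions are seed-deterministic", {
  set.seed(25)
  x <- matrix(rnorm(200), 40, 5)
  y <- factor(rep(c("nodule", "nonnodule"), 20), c("nodule", "nonnodule"))
  m1 <- trainClassifier(x, y, "RF", seed = 9)
  m2 <- trainClassifier(x, y, "RF", seed = 9)
  xn <- matrix(rnorm(50), 10, 5)
  expect_identical(predictClassifier(m1, xn), predictClassifier(m2, xn))
  expect_error(trainClassifier(x, factor(rep("nodule", 40))), "class")
})

test_that("the canonical grid has 36 uniquely named combinations", {
  g <- canonicalCombos()
  expect_equal(nrow(g), 36L)
  expect_equal(anyDuplicated(g$combo), 0L)
  expect_setequal(unique(g$classifier), c("SVM", "KNN", "DT", "RF"))
  expect_true("SVM_ExHOG_CNN" %in% g$combo)
  expect_equal(sum(lengths(g$featureSet) == 1), 16L)  # 4 singletons x 4 classifiers
})

test_that("grid results cover every combo and counts sum to pooled test sizes", {
  se <- makeFeatureSE(40)
  res <- runGrid(se, splitScheme(seed = 1), canonicalCombos()[c(2, 11, 20, 29), ])
  expect_equal(nrow(res), 4L)
  n <- 40
  pooledN <- sum(vapply(c(10, 20, 30, 40, 50) / 100,
                        function(f) n - 2 * round(n / 2 * f), 0))
  expect_true(all(res$tp + res$fp + res$fn + res$tn == pooledN))
  # determinism given (dataset, seed)
  res2 <- runGrid(se, splitScheme(seed = 1), canonicalCombos()[c(2, 11, 20, 29), ])
  expect_identical(res[, c("combo", "tp", "fp", "fn", "tn")],
                   res2[, c("combo", "tp", "fp", "fn", "tn")])
  expect_error(runGrid(se, splitScheme(trainFractions = 1, seed = 1),
                       canonicalCombos()[1, ]), "empty")
})

test_that("an injected perfect classifier yields a perfect pooled matrix", {
  se <- makeFeatureSE(30)
  perfect <- list(fit = function(x, y, seed) {
    # memorize the decision rule carried by the class signal feature
    list(sign = stats::median(x[y == "nodule", 1]) >
           stats::median(x[y == "nonnodule", 1]))
  }, predict = function(model, x) {
    pos <- if (model$sign) x[, 1] > 0 else x[, 1] < 0
    factor(ifelse(pos, "nodule", "nonnodule"), c("nodule", "nonnodule"))
  })
  res <- runGrid(se, splitScheme(seed = 2),
                 canonicalCombos()[canonicalCombos()$combo == "SVM_HOG", ],
                 classifiers = list(SVM = perfect))
  expect_equal(res$fp, 0L)
  expect_equal(res$fn, 0L)
  expect_equal(res$accuracy, 100)
  expect_equal(res$fscore, 100)
  expect_equal(res$kappa, 100)
})

test_that("standardization statistics come from the train split only", {
  se <- makeFeatureSE(30)
  seen <- new.env()
  spy <- list(fit = function(x, y, seed) {
    seen$trainMeans <- c(seen$trainMeans, abs(colMeans(x[, 1:5])))
    NULL
  }, predict = function(model, x) {
    factor(rep("nodule", nrow(x)), c("nodule", "nonnodule"))
  })
  invisible(runGrid(se, splitScheme(seed = 3),
                    canonicalCombos()[canonicalCombos()$combo == "KNN_LBP", ],
                    classifiers = list(KNN = spy)))
  expect_lt(max(seen$trainMeans), 1e-10)
})
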