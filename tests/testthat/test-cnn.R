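test_that("the default architecture composes 50 -> 1 with 2 outputs and 40 features", {
  spec <- buildCNNSpec()
  expect_equal(shapeTrace(spec), c(50L, 46L, 23L, 19L, 9L, 5L, 5L, 4L, 1L))
  expect_equal(spec$layers[[1]]$filters, 20L)
  expect_equal(spec$layers[[1]]$kernel, 5L)
  m <- initCNN(spec, seed = 1)
  fw <- cnnForward(m, matrix(runif(2500), 50, 50))
  expect_equal(dim(fw$probs), c(2L, 1L))
  expect_equal(sum(fw$probs), 1, tolerance = 1e-9)
  expect_equal(nrow(fw$features), 40L)
  expect_length(cnnFeatures(m, matrix(runif(2500), 50, 50)), 40L)
  expect_error(cnnForward(m, matrix(0, 48, 48)), "50 x 50")
})

test_that("softmax probabilities are symmetric for all-zero parameters", {
  m <- initCNN(seed = 2)
  m@params$conv <- lapply(m@params$conv, function(l) {
    l$W[] <- 0; l$b[] <- 0; l
  })
  m@params$projW[] <- 0
  m@params$projB[] <- 0
  fw <- cnnForward(m, matrix(runif(2500), 50, 50))
  expect_equal(as.vector(fw$probs), c(0.5, 0.5))
  expect_true(all(fw$features == 0))
})

test_that("convolution layers match the quadruple-loop oracle", {
  set.seed(31)
  X <- array(runif(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (stride in 1:2) {
    got <- noduleFusion:::convForward(X, W, b, stride)$out
    expect_equal(got, oracleConv(X, W, b, stride), tolerance = 1e-12)
  }
})

test_that("analytic gradients match central differences on a tiny spec", {
  spec <- list(inputSize = 6L, classes = 2L, layers = list(
    list(type = "conv", filters = 2L, kernel = 3L, stride = 1L),
    list(type = "relu"),
    list(type = "pool", kernel = 2L, stride = 2L)))
  m <- initCNN(spec, seed = 13)
  set.seed(14)
  X <- array(runif(6 * 6 * 1 * 4), c(6, 6, 1, 4))
  Y <- c(1L, 2L, 1L, 2L)
  lg <- noduleFusion:::cnnLossGrad(m@params, X, Y, spec)
  numGrad <- function(mutate, n) vapply(seq_len(n), function(k) {
    e <- 1e-5
    lp <- noduleFusion:::cnnLossGrad(mutate(m@params, k, e), X, Y, spec)$loss
    lm <- noduleFusion:::cnnLossGrad(mutate(m@params, k, -e), X, Y, spec)$loss
    (lp - lm) / (2 * e)
  }, 0)
  relErr <- function(a, b) max(abs(a - b) / pmax(abs(a), abs(b), 1e-6))
  gW <- numGrad(function(p, k, e) { p$conv[[1]]$W[k] <- p$conv[[1]]$W[k] + e; p },
                length(m@params$conv[[1]]$W))
  expect_lt(relErr(gW, as.vector(lg$grads$conv[[1]]$dW)), 1e-4)
  gb <- numGrad(function(p, k, e) { p$conv[[1]]$b[k] <- p$conv[[1]]$b[k] + e; p }, 2)
  expect_lt(relErr(gb, lg$grads$conv[[1]]$db), 1e-4)
  gP <- numGrad(function(p, k, e) { p$projW[k] <- p$projW[k] + e; p },
                length(m@params$projW))
  expect_lt(relErr(gP, as.vector(lg$grads$projW)), 1e-4)
})

test_that("training separates bright from dark patches and is seed-deterministic", {
  sep <- makeSeparablePatches(n = 40)
  m1 <- trainCNN(sep$X, sep$y, maxIterations = 200L, seed = 7)
  expect_equal(mean(cnnPredict(m1, sep$X) == sep$y), 1.0)
  m2 <- trainCNN(sep$X, sep$y, maxIterations = 200L, seed = 7)
  expect_identical(tail(m1@trace$loss, 1), tail(m2@trace$loss, 1))
  expect_identical(m1@params$projW, m2@params$projW)
  expect_equal(nrow(m1@trace), 200L)
  expect_error(trainCNN(sep$X, rep("nodule", 40)), "2 classes")
})

test_that("full-batch loss decreases on a toy problem with a small step", {
  sep <- makeSeparablePatches(n = 8, size = 16)
  spec <- list(inputSize = 16L, classes = 2L, layers = list(
    list(type = "conv", filters = 4L, kernel = 5L, stride = 1L),
    list(type = "relu"),
    list(type = "pool", kernel = 2L, stride = 2L)))
  m <- trainCNN(sep$X, sep$y, spec = spec, learningRate = 0.005,
                batchSize = 8L, maxIterations = 60L, seed = 3)
  # full-batch training: the trace loss is the exact loss before each step
  l <- m@trace$loss
  checkpoints <- c(1L, 30L, 60L)
  expect_true(all(diff(l[checkpoints]) < 0))
})

test_that("feature vector equals the forward pass features and parameters round-trip", {
  m <- initCNN(seed = 5)
  p <- matrix(runif(2500), 50, 50)
  expect_identical(cnnFeatures(m, p), drop(cnnForward(m, p)$features))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cnn.rds")
  saveCNN(m, f)
  m2 <- loadCNN(f)
  expect_identical(m2@params, m@params)
  expect_identical(cnnForward(m2, p)$probs, cnnForward(m, p)$probs)
})
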