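test_that("gradients match closed forms on constant and ramp patches", {
  g0 <- computeGradients(matrix(0.4, 10, 10))
  expect_true(all(g0$magnitude == 0))
  expect_true(all(g0$thetaSigned == 0))
  # intensity increasing along x (columns): interior Ix = 2/width, Iy = 0
  w <- 10
  ramp <- matrix(rep(seq_len(w) / w, each = w), w, w)  # column j = j/w
  g <- computeGradients(ramp)
  inner <- 2:(w - 1)
  expect_equal(as.vector(g$Ix[, inner]), rep(2 / w, w * (w - 2)))
  expect_true(all(g$Iy == 0))
  expect_true(all(g$thetaUnsigned[, inner] == 0))
})

test_that("gradients equal the per-pixel double-loop oracle", {
  set.seed(8)
  for (rep in 1:3) {
    p <- matrix(runif(64), 8, 8)
    g <- computeGradients(p)
    o <- oracleGradients(p)
    for (f in names(o)) expect_equal(g[[f]], o[[f]], tolerance = 1e-12)
  }
  expect_error(computeGradients(matrix(0, 2, 5)), "3 x 3")
})

test_that("HOG has the canonical geometry: 1296 features, non-negative", {
  set.seed(1)
  d <- hogDescriptor(matrix(runif(784), 28, 28))
  expect_length(d, 1296L)
  expect_true(all(d >= 0))
  expect_identical(hogDescriptor(matrix(0.5, 28, 28)), rep(0, 1296))
  expect_error(hogDescriptor(matrix(0, 27, 27)), "multiple")
  expect_error(hogDescriptor(matrix(0, 28, 26)), "square")
})

test_that("a vertical step edge votes into the bin containing 0 degrees", {
  p <- cbind(matrix(0.2, 28, 14), matrix(0.8, 28, 14))
  d <- hogDescriptor(p)
  m <- matrix(d, nrow = 9)  # columns = cells within blocks
  active <- which(colSums(m) > 0)
  for (j in active)
    expect_equal(m[1, j], max(m[, j]))
})

test_that("ExHOG folds sum and absolute difference of opposite signed bins", {
  set.seed(2)
  p <- matrix(runif(784), 28, 28)
  d <- exhogDescriptor(p)
  expect_length(d, 648L)
  expect_true(all(d >= 0))
  expect_identical(exhogDescriptor(matrix(0.1, 28, 28)), rep(0, 648))
  raw <- exhogDescriptor(p, normalize = FALSE)
  for (cell in c(0L, 7L, 35L)) {
    cr <- cell %/% 6L; cc <- cell %% 6L
    h <- oracleExhogCellRaw(p, cr, cc)
    expect_equal(raw[(cell * 18 + 1):(cell * 18 + 9)], h[1:9] + h[10:18],
                 tolerance = 1e-10)
    expect_equal(raw[(cell * 18 + 10):(cell * 18 + 18)], abs(h[1:9] - h[10:18]),
                 tolerance = 1e-10)
  }
})

test_that("LBP matches hand-computed codes and sums to one", {
  # center 5; clockwise from top-left: 6,7,8,4,3,2,1,5 -> bits 1,1,1,0,0,0,0,1
  m <- matrix(c(6, 7, 8,
                5, 5, 4,
                1, 2, 3), 3, 3, byrow = TRUE)
  h <- lbpDescriptor(m)
  expect_length(h, 256L)
  expect_equal(which(h > 0) - 1L, 135L)
  # constant patch: all neighbours >= center -> code 255 everywhere
  hc <- lbpDescriptor(matrix(0.3, 12, 12))
  expect_equal(hc[256], 1)
  expect_equal(sum(hc), 1)
  expect_error(lbpDescriptor(matrix(0, 2, 2)), "3 x 3")
})

test_that("descriptors equal their brute-force oracles on random patches", {
  set.seed(42)
  for (rep in 1:5) {
    p <- matrix(runif(144), 12, 12)
    expect_equal(hogDescriptor(p), oracleHOG(p), tolerance = 1e-10)
    expect_equal(exhogDescriptor(p), oracleExHOG(p), tolerance = 1e-10)
    expect_equal(lbpDescriptor(p), oracleLBP(p), tolerance = 1e-12)
  }
})

test_that("descriptors are invariant to intensity shift; HOG/ExHOG to scale; LBP to monotone affine", {
  set.seed(9)
  p <- matrix(runif(784), 28, 28) * 0.5
  for (f in list(hogDescriptor, exhogDescriptor, lbpDescriptor))
    expect_equal(f(p), f(p + 0.3), tolerance = 1e-9)
  expect_equal(hogDescriptor(p), hogDescriptor(p * 1.7), tolerance = 1e-6)
  expect_equal(exhogDescriptor(p), exhogDescriptor(p * 1.7), tolerance = 1e-6)
  expect_identical(lbpDescriptor(p), lbpDescriptor(p * 1.9 + 0.01))
})
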