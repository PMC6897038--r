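# Brute-force reference implementations used as independent oracles.
# Everything here is written as explicit per-pixel double loops, deliberately
# independent of the vectorized code paths in the package.

oracleGradients <- function(patch) {
  H <- nrow(patch); W <- ncol(patch)
  Ix <- Iy <- M <- thS <- thU <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      cl <- max(1, c - 1); cr <- min(W, c + 1)
      ru <- max(1, r - 1); rd <- min(H, r + 1)
      Ix[r, c] <- patch[r, cr] - patch[r, cl]
      Iy[r, c] <- patch[rd, c] - patch[ru, c]
      M[r, c] <- sqrt(Ix[r, c]^2 + Iy[r, c]^2)
      if (M[r, c] > 0) {
        thS[r, c] <- atan2(Iy[r, c], Ix[r, c]) %% (2 * pi)
        thU[r, c] <- thS[r, c] %% pi
      }
    }
  }
  list(Ix = Ix, Iy = Iy, magnitude = M, thetaSigned = thS, thetaUnsigned = thU)
}

# interpolated vote of one pixel into a circular histogram
oracleVote <- function(h, theta, mag, nbins, range) {
  bw <- range / nbins
  t <- theta / bw - 0.5
  b0 <- floor(t)
  w1 <- t - b0
  i0 <- (b0 %% nbins) + 1
  i1 <- ((b0 + 1) %% nbins) + 1
  h[i0] <- h[i0] + mag * (1 - w1)
  h[i1] <- h[i1] + mag * w1
  h
}

oracleCellHistogram <- function(g, rows, cols, nbins, range, signed) {
  h <- numeric(nbins)
  th <- if (signed) g$thetaSigned else g$thetaUnsigned
  for (r in rows) for (c in cols)
    h <- oracleVote(h, th[r, c], g$magnitude[r, c], nbins, range)
  h
}

oracleHOG <- function(patch, cellSize = 4, blockCells = 2, nbins = 9,
                      eps = 1e-12) {
  g <- oracleGradients(patch)
  nc <- nrow(patch) / cellSize
  hists <- list()
  for (ci in 1:nc) for (cj in 1:nc)
    hists[[(ci - 1) * nc + cj]] <- oracleCellHistogram(
      g, ((ci - 1) * cellSize + 1):(ci * cellSize),
      ((cj - 1) * cellSize + 1):(cj * cellSize), nbins, pi, signed = FALSE)
  out <- c()
  nb <- nc - blockCells + 1
  for (bi in 1:nb) for (bj in 1:nb) {
    v <- c()
    for (ri in 0:(blockCells - 1)) for (rj in 0:(blockCells - 1))
      v <- c(v, hists[[(bi + ri - 1) * nc + (bj + rj)]])
    out <- c(out, v / sqrt(sum(v^2) + eps^2))
  }
  out
}

# unnormalized signed 18-bin histogram of one ExHOG cell (floor grid rule)
oracleExhogCellRaw <- function(patch, cellRow, cellCol, cells = 6, nbins = 18) {
  g <- oracleGradients(patch)
  n <- nrow(patch)
  h <- numeric(nbins)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if (min(cells - 1, floor(cells * (r - 1) / n)) == cellRow &&
        min(cells - 1, floor(cells * (c - 1) / n)) == cellCol)
      h <- oracleVote(h, g$thetaSigned[r, c], g$magnitude[r, c], nbins, 2 * pi)
  }
  h
}

oracleExHOG <- function(patch, cells = 6, nbins = 18, clip = 0.2, eps = 1e-12) {
  out <- c()
  half <- nbins / 2
  for (cr in 0:(cells - 1)) for (cc in 0:(cells - 1)) {
    h <- oracleExhogCellRaw(patch, cr, cc, cells, nbins)
    v <- c(h[1:half] + h[(half + 1):nbins], abs(h[1:half] - h[(half + 1):nbins]))
    v <- v / sqrt(sum(v^2) + eps^2)
    v <- pmin(v, clip)
    v <- v / sqrt(sum(v^2) + eps^2)
    out <- c(out, v)
  }
  out
}

oracleLBP <- function(patch) {
  H <- nrow(patch); W <- ncol(patch)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  h <- numeric(256)
  for (r in 2:(H - 1)) for (c in 2:(W - 1)) {
    code <- 0
    for (p in 1:8)
      if (patch[r + offs[[p]][1], c + offs[[p]][2]] >= patch[r, c])
        code <- code + 2^(p - 1)
    h[code + 1] <- h[code + 1] + 1
  }
  h / sum(h)
}

# Eq.-style quadruple-loop valid convolution of one image, one filter bank
oracleConv <- function(X, W, b, stride = 1) {
  H <- dim(X)[1]; C <- dim(X)[3]; N <- dim(X)[4]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  Ho <- (H - k) %/% stride + 1
  Wo <- (dim(X)[2] - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (i in 1:Ho) for (j in 1:Wo) {
    s <- b[co]
    for (ci in 1:C) for (di in 0:(k - 1)) for (dj in 0:(k - 1))
      s <- s + X[(i - 1) * stride + 1 + di, (j - 1) * stride + 1 + dj, ci, n] *
        W[di + 1, dj + 1, ci, co]
    out[i, j, co, n] <- s
  }
  out
}

# Cohen's kappa directly from label vectors (agreement/chance tally)
oracleKappa <- function(truth, pred) {
  pa <- mean(truth == pred)
  lv <- unique(c(truth, pred))
  pe <- 0
  for (l in lv) pe <- pe + mean(truth == l) * mean(pred == l)
  (pa - pe) / (1 - pe)
}

# small labelled patch set: bright blob-ish vs dark, trivially separable
makeSeparablePatches <- function(n = 40, size = 50, seed = 5) {
  set.seed(seed)
  y <- rep(c("nodule", "nonnodule"), each = n / 2)
  X <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    base <- if (y[i] == "nodule") 0.8 else 0.2
    X[, , i] <- pmin(1, pmax(0, base + matrix(rnorm(size * size, 0, 0.05),
                                              size, size)))
  }
  list(X = X, y = factor(y, levels = c("nodule", "nonnodule")))
}
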