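#' Per-pixel image gradients, magnitude and orientation
#'
#' Derivatives use the centered 1-D kernels (-1 0 1) horizontally and
#' (-1 0 1)' vertically, with edge replication at the borders (so border
#' derivatives are one-sided differences). The magnitude is
#' \code{sqrt(Ix^2 + Iy^2)}; the signed orientation is the two-argument
#' arctangent of (Iy, Ix) mapped to \[0, 2*pi), and the unsigned orientation
#' is the signed one modulo pi (opposite directions share an angle). Pixels
#' with zero magnitude get orientation 0 by convention.
#'
#' @param patch numeric matrix, at least 3 x 3. Rows index y (vertical),
#'   columns index x (horizontal).
#' @return list with matrices \code{Ix}, \code{Iy}, \code{magnitude},
#'   \code{thetaSigned} (in \[0, 2*pi)) and \code{thetaUnsigned} (in
#'   \[0, pi)).
#' @examples
#' ramp <- matrix(rep(seq_len(8) / 8, each = 8), 8, 8)  # increases along x
#' g <- computeGradients(ramp)
#' g$Ix[4, 4] * 8   # interior centered difference = 2
#' @export
computeGradients <- function(patch) {
  if (!is.matrix(patch) || !is.numeric(patch)) stop("patch must be a numeric matrix")
  H <- nrow(patch); W <- ncol(patch)
  if (H < 3L || W < 3L) stop("patch must be at least 3 x 3")
  Ix <- patch[, c(2:W, W)] - patch[, c(1, 1:(W - 1))]
  Iy <- patch[c(2:H, H), ] - patch[c(1, 1:(H - 1)), ]
  M <- sqrt(Ix^2 + Iy^2)
  th <- atan2(Iy, Ix) %% (2 * pi)
  th[M == 0] <- 0
  list(Ix = Ix, Iy = Iy, magnitude = M,
       thetaSigned = th, thetaUnsigned = th %% pi)
}

# Magnitude-weighted orientation histogram with linear interpolation between
# the two nearest bin centers; bins are circular over [0, range) with centers
# at (b + 0.5) * range / nbins.
orientationHistogram <- function(theta, mag, nbins, range) {
  bw <- range / nbins
  t <- theta / bw - 0.5
  b0 <- floor(t)
  w1 <- t - b0
  i0 <- (b0 %% nbins) + 1L
  i1 <- ((b0 + 1) %% nbins) + 1L
  h <- numeric(nbins)
  votes0 <- rowsum(as.vector(mag * (1 - w1)), as.vector(i0))
  votes1 <- rowsum(as.vector(mag * w1), as.vector(i1))
  h[as.integer(rownames(votes0))] <- votes0[, 1]
  h[as.integer(rownames(votes1))] <- h[as.integer(rownames(votes1))] + votes1[, 1]
  h
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Standard HOG on a square patch: 4 x 4-pixel cells, each with a 9-bin
#' unsigned orientation histogram over \[0, 180) degrees with
#' magnitude-weighted, linearly interpolated votes; blocks of 2 x 2 cells
#' (8 x 8 pixels) advanced with a stride of 4 pixels (one cell); each block
#' is L2-normalized (with an epsilon guard, so all-zero blocks stay zero) and
#' the normalized blocks are concatenated. On the 28 x 28 working size this
#' gives 6 x 6 block positions and a descriptor of exactly
#' 36 blocks x 4 cells x 9 bins = 1296 non-negative values.
#'
#' @param patch square numeric matrix whose side is a multiple of
#'   \code{cellSize} and at least \code{blockCells * cellSize} (the pipeline
#'   uses 28 x 28; see [resizePatch()]).
#' @param cellSize cell side in pixels (default 4).
#' @param blockCells cells per block side (default 2).
#' @param nbins orientation bins per cell (default 9).
#' @param eps normalization guard (default 1e-12).
#' @return numeric descriptor vector (length 1296 for a 28 x 28 patch).
#' @examples
#' length(hogDescriptor(matrix(runif(28 * 28), 28, 28)))
#' @export
hogDescriptor <- function(patch, cellSize = 4L, blockCells = 2L, nbins = 9L,
                          eps = 1e-12) {
  assertSquarePatch(patch, minSize = 3L)
  n <- nrow(patch)
  if (n %% cellSize != 0L)
    stop("patch side (", n, ") must be a multiple of the cell size (", cellSize, ")")
  nc <- n %/% cellSize
  if (nc < blockCells)
    stop("patch too small: needs at least ", blockCells * cellSize, " pixels per side")
  g <- computeGradients(patch)
  cellHist <- array(0, c(nbins, nc, nc))
  for (ci in seq_len(nc)) {
    rows <- ((ci - 1L) * cellSize + 1L):(ci * cellSize)
    for (cj in seq_len(nc)) {
      cols <- ((cj - 1L) * cellSize + 1L):(cj * cellSize)
      cellHist[, ci, cj] <- orientationHistogram(
        g$thetaUnsigned[rows, cols], g$magnitude[rows, cols], nbins, pi)
    }
  }
  nb <- nc - blockCells + 1L
  out <- numeric(nb * nb * blockCells^2 * nbins)
  blockLen <- blockCells^2 * nbins
  k <- 0L
  for (bi in seq_len(nb)) {
    for (bj in seq_len(nb)) {
      v <- numeric(blockLen)
      m <- 0L
      for (ri in 0:(blockCells - 1L)) {
        for (rj in 0:(blockCells - 1L)) {
          v[(m * nbins + 1L):((m + 1L) * nbins)] <- cellHist[, bi + ri, bj + rj]
          m <- m + 1L
        }
      }
      v <- v / sqrt(sum(v^2) + eps^2)
      out[(k * blockLen + 1L):((k + 1L) * blockLen)] <- v
      k <- k + 1L
    }
  }
  out
}

#' Extended-HOG descriptor with signed-orientation folding
#'
#' Builds, for each cell of a 6 x 6 cell grid (pixels are assigned to cell
#' \code{floor(6 * x / side)}, so fractional cell sizes are handled exactly),
#' a signed 18-bin orientation histogram over \[0, 360) degrees with
#' magnitude-weighted interpolated votes, and folds opposite bins i and i + 9
#' into 9 sum bins \code{h(i) + h(i + 9)} followed by 9 absolute-difference
#' bins \code{|h(i) - h(i + 9)|}. The sum bins are the unsigned HOG
#' histogram; the difference bins cancel when bright-to-dark and
#' dark-to-bright edges balance, which removes edge-polarity ambiguity. Each
#' 18-value cell vector is L2-normalized, clipped at \code{clip} and
#' re-normalized (L2-hys). Concatenating the 36 cells gives exactly
#' 36 x 18 = 648 non-negative values.
#'
#' @param patch square numeric matrix (the pipeline uses 28 x 28).
#' @param cells cell-grid side (default 6).
#' @param nbins signed orientation bins before folding (default 18; must be
#'   even).
#' @param clip clipping threshold relative to the cell L2 norm (default 0.2).
#' @param eps normalization guard (default 1e-12).
#' @param normalize if \code{FALSE}, return the raw folded (unnormalized)
#'   bins, useful for checking the fold identity against the signed
#'   histogram.
#' @return numeric descriptor vector (length 648 with the defaults).
#' @examples
#' length(exhogDescriptor(matrix(runif(28 * 28), 28, 28)))
#' @export
exhogDescriptor <- function(patch, cells = 6L, nbins = 18L, clip = 0.2,
                            eps = 1e-12, normalize = TRUE) {
  assertSquarePatch(patch, minSize = 3L)
  if (nbins %% 2L != 0L) stop("nbins must be even")
  n <- nrow(patch)
  if (n < cells) stop("patch side must be at least the cell-grid side")
  g <- computeGradients(patch)
  half <- nbins %/% 2L
  # pixel-to-cell assignment (0-based floor rule)
  cellOf <- function(i) pmin(cells - 1L, floor(cells * (i - 1L) / n))
  ri <- cellOf(row(patch)); cj <- cellOf(col(patch))
  cellId <- ri * cells + cj  # 0-based, row-major
  out <- numeric(cells * cells * nbins)
  for (id in 0:(cells * cells - 1L)) {
    sel <- cellId == id
    h <- orientationHistogram(g$thetaSigned[sel], g$magnitude[sel],
                              nbins, 2 * pi)
    v <- c(h[1:half] + h[(half + 1):nbins],
           abs(h[1:half] - h[(half + 1):nbins]))
    if (normalize) {
      v <- v / sqrt(sum(v^2) + eps^2)
      v <- pmin(v, clip)
      v <- v / sqrt(sum(v^2) + eps^2)
    }
    out[(id * nbins + 1L):((id + 1L) * nbins)] <- v
  }
  out
}

#' Local-binary-pattern texture descriptor
#'
#' For every interior pixel, the eight neighbours are compared with the
#' center: a neighbour greater than or equal to the center contributes 1,
#' otherwise 0. Neighbours are enumerated clockwise starting at the top-left,
#' with the top-left as the least-significant bit, giving a code
#' \code{sum(s_p * 2^p)} in 0..255. The descriptor is the 256-bin code
#' histogram normalized to sum 1, which is exactly invariant under any
#' strictly increasing (and, with the >= tie rule, any non-decreasing affine
#' with positive slope) intensity transformation.
#'
#' @param patch numeric matrix, at least 3 x 3.
#' @return numeric vector of length 256 summing to 1.
#' @examples
#' h <- lbpDescriptor(matrix(0.5, 8, 8))
#' which(h > 0) - 1  # constant patch: every code is 255
#' @export
lbpDescriptor <- function(patch) {
  if (!is.matrix(patch) || !is.numeric(patch)) stop("patch must be a numeric matrix")
  H <- nrow(patch); W <- ncol(patch)
  if (H < 3L || W < 3L) stop("patch must be at least 3 x 3")
  rows <- 2:(H - 1); cols <- 2:(W - 1)
  center <- patch[rows, cols]
  # clockwise from top-left: (dr, dc) offsets
  off <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
              c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, length(rows), length(cols))
  for (p in seq_along(off)) {
    nb <- patch[rows + off[[p]][1], cols + off[[p]][2]]
    code <- code + (nb >= center) * (2L^(p - 1L))
  }
  h <- tabulate(as.vector(code) + 1L, nbins = 256L)
  h / sum(h)
}

#' Canonical descriptor lengths
#'
#' The fixed feature-vector lengths of the four extractors at their working
#' sizes: HOG 1296, ExHOG 648, LBP 256, CNN 40.
#'
#' @return named integer vector.
#' @export
descriptorLengths <- function() {
  c(HOG = 1296L, ExHOG = 648L, CNN = 40L, LBP = 256L)
}
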