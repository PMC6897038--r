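#' Default architecture of the small convolutional network
#'
#' Nine layers: conv(20 filters, 5 x 5, stride 1) -> max-pool(2 x 2, stride
#' 2) -> conv(32, 5 x 5) -> max-pool(2 x 2, stride 2) -> conv(32, 5 x 5) ->
#' ReLU -> max-pool(2 x 2, stride 1) -> conv(40, 4 x 4) -> linear projection
#' to 2 classes + softmax. All convolutions are "valid" (no padding), so the
#' spatial trace on a 50 x 50 x 1 input is
#' 50 -> 46 -> 23 -> 19 -> 9 -> 5 -> 5 -> 4 -> 1 and the forward output is
#' 1 x 1 x 2. The 40 activations entering the projection are the CNN feature
#' vector used in fusion.
#'
#' @param inputSize input side length in pixels (default 50).
#' @param classes number of output classes (default 2).
#' @return a list with elements \code{inputSize}, \code{classes} and
#'   \code{layers} (each layer a list with a \code{type} of "conv", "pool" or
#'   "relu").
#' @examples
#' shapeTrace(buildCNNSpec())
#' @export
buildCNNSpec <- function(inputSize = 50L, classes = 2L) {
  list(
    inputSize = as.integer(inputSize),
    classes = as.integer(classes),
    layers = list(
      list(type = "conv", filters = 20L, kernel = 5L, stride = 1L),
      list(type = "pool", kernel = 2L, stride = 2L),
      list(type = "conv", filters = 32L, kernel = 5L, stride = 1L),
      list(type = "pool", kernel = 2L, stride = 2L),
      list(type = "conv", filters = 32L, kernel = 5L, stride = 1L),
      list(type = "relu"),
      list(type = "pool", kernel = 2L, stride = 1L),
      list(type = "conv", filters = 40L, kernel = 4L, stride = 1L)
    )
  )
}

#' Spatial size after each layer
#'
#' Valid convolution maps side F to F - C + 1; pooling maps F to
#' \code{floor((F - C) / stride) + 1} (trailing rows/columns that do not fill
#' a window are dropped); ReLU keeps the size.
#'
#' @param spec a network spec from [buildCNNSpec()].
#' @return integer vector: input side followed by the side after each layer.
#' @export
shapeTrace <- function(spec) {
  s <- spec$inputSize
  out <- s
  for (ly in spec$layers) {
    s <- switch(ly$type,
      conv = s - ly$kernel + 1L,
      pool = (s - ly$kernel) %/% ly$stride + 1L,
      relu = s,
      stop("unknown layer type: ", ly$type))
    out <- c(out, s)
  }
  as.integer(out)
}

# channel count after the feature layers
finalChannels <- function(spec) {
  ch <- 1L
  for (ly in spec$layers) if (ly$type == "conv") ch <- ly$filters
  ch
}

#' Initialize network parameters
#'
#' Convolution weights are drawn from N(0, 2 / fan_in) (He initialization for
#' ReLU-family nets), biases start at zero; the projection uses
#' N(0, 1 / n_features). Deterministic given the seed.
#'
#' @param spec a network spec from [buildCNNSpec()].
#' @param seed integer seed.
#' @return a [CNNModel-class] with untrained parameters.
#' @export
initCNN <- function(spec = buildCNNSpec(), seed = 0L) {
  trace <- shapeTrace(spec)
  if (any(trace < 1L))
    stop("spec does not compose: spatial size drops below 1 (trace: ",
         paste(trace, collapse = " -> "), ")")
  withSeed(seed, {
    params <- list(conv = list(), projW = NULL, projB = NULL)
    cin <- 1L
    for (ly in spec$layers) {
      if (ly$type == "conv") {
        k <- ly$kernel
        fanIn <- k * k * cin
        W <- array(rnorm(k * k * cin * ly$filters, 0, sqrt(2 / fanIn)),
                   c(k, k, cin, ly$filters))
        params$conv[[length(params$conv) + 1L]] <- list(W = W, b = numeric(ly$filters))
        cin <- ly$filters
      }
    }
    nfeat <- finalChannels(spec) * trace[length(trace)]^2
    params$projW <- matrix(rnorm(spec$classes * nfeat, 0, sqrt(1 / nfeat)),
                           spec$classes, nfeat)
    params$projB <- numeric(spec$classes)
    new("CNNModel", spec = spec, params = params,
        trace = data.frame(iteration = integer(), loss = numeric(),
                           accuracy = numeric()),
        classLevels = c("nodule", "nonnodule"))
  })
}

# ---- low-level layer engine ------------------------------------------------
# Tensors are arrays (H, W, C, N). Convolution uses an im2col layout: every
# k x k x C patch becomes one ROW of a (Ho*Wo*N) x (k*k*C) matrix, so the
# forward pass, the weight gradient and the input-patch gradient are each a
# single BLAS product with no large transposes. Gather indices depend only on
# the tensor geometry and are cached across calls (SGD reuses them every
# iteration).

.layerCache <- new.env(parent = emptyenv())

im2colIndex <- function(H, W, C, N, k, stride) {
  key <- paste(H, W, C, N, k, stride, sep = "_")
  hit <- .layerCache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * H, "+"))
  off <- as.vector(outer(off, (0:(C - 1L)) * H * W, "+"))    # k*k*C
  tl <- as.vector(outer(seq(1L, by = stride, length.out = Ho),
                        (seq(1L, by = stride, length.out = Wo) - 1L) * H, "+"))
  tl <- as.vector(outer(tl, (0:(N - 1L)) * H * W * C, "+"))  # Ho*Wo*N
  idxT <- outer(tl, off, "+")                  # (Ho*Wo*N) x (k*k*C), patch rows
  storage.mode(idxT) <- "integer"
  val <- list(idxT = idxT, idxVec = as.vector(idxT), Ho = Ho, Wo = Wo)
  .layerCache[[key]] <- val
  val
}

convForward <- function(X, W, b, stride = 1L) {
  d <- dim(X); k <- dim(W)[1]; Cout <- dim(W)[4]
  if (dim(W)[3] != d[3]) stop("conv weight/input channel mismatch")
  ii <- im2colIndex(d[1], d[2], d[3], d[4], k, stride)
  colsT <- gather_idx(X, ii$idxVec)
  dim(colsT) <- dim(ii$idxT)                       # (Ho*Wo*N) x (k*k*C)
  Wm <- matrix(W, k * k * d[3], Cout)              # (k*k*C) x Cout
  YT <- colsT %*% Wm                               # (Ho*Wo*N) x Cout
  for (j in seq_len(Cout)) YT[, j] <- YT[, j] + b[j]
  Y <- array(YT, c(ii$Ho, ii$Wo, d[4], Cout))
  list(out = aperm(Y, c(1, 2, 4, 3)), colsT = colsT, ii = ii)
}

convBackward <- function(dOut, X, W, stride, cache, needInputGrad = TRUE) {
  d <- dim(X); k <- dim(W)[1]; Cout <- dim(W)[4]
  dYT <- aperm(dOut, c(1, 2, 4, 3))
  dim(dYT) <- c(length(dYT) %/% Cout, Cout)        # (Ho*Wo*N) x Cout
  dW <- crossprod(cache$colsT, dYT)                # (k*k*C) x Cout
  db <- colSums(dYT)
  dX <- NULL
  if (needInputGrad) {
    Wm <- matrix(W, k * k * d[3], Cout)
    dColsT <- tcrossprod(dYT, Wm)                  # (Ho*Wo*N) x (k*k*C)
    dX <- array(0, d)
    # col2im: accumulate patch gradients back onto the (overlapping) input
    scatter_add(dX, cache$ii$idxVec, dColsT)
  }
  list(dX = dX, dW = array(dW, c(k, k, d[3], Cout)), db = db)
}

# Max pooling reuses the gather machinery with each channel of each image
# treated as its own single-channel plane, so one row of V is one k x k
# window and the output is the row maximum.
poolForward <- function(X, k = 2L, stride = 2L) {
  d <- dim(X)
  ii <- im2colIndex(d[1], d[2], 1L, d[3] * d[4], k, stride)
  V <- gather_idx(X, ii$idxVec)
  dim(V) <- dim(ii$idxT)                           # (Ho*Wo*C*N) x (k*k)
  outVec <- row_max(V)
  list(out = array(outVec, c(ii$Ho, ii$Wo, d[3], d[4])),
       outVec = outVec, V = V, ii = ii)
}

poolBackward <- function(dOut, X, k, stride, cache) {
  dX <- array(0, dim(X))
  # each window's gradient goes to its (first) argmax position
  pool_scatter(dX, cache$V, cache$outVec, cache$ii$idxT, as.vector(dOut))
  dX
}

softmaxCols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))  # overflow guard
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Forward through all feature layers. X: (H, W, 1, N). Returns per-layer
# caches when `keep` so the backward pass can reuse them.
cnnForwardCore <- function(params, X, spec, keep = FALSE) {
  caches <- if (keep) vector("list", length(spec$layers)) else NULL
  a <- X
  ci <- 0L
  for (li in seq_along(spec$layers)) {
    ly <- spec$layers[[li]]
    if (ly$type == "conv") {
      ci <- ci + 1L
      fw <- convForward(a, params$conv[[ci]]$W, params$conv[[ci]]$b, ly$stride)
      if (keep) caches[[li]] <- list(input = a, fw = fw)
      a <- fw$out
    } else if (ly$type == "pool") {
      fw <- poolForward(a, ly$kernel, ly$stride)
      if (keep) caches[[li]] <- list(input = a, fw = fw)
      a <- fw$out
    } else if (ly$type == "relu") {
      if (keep) caches[[li]] <- list(input = a)
      a <- pmax(a, 0)
    }
  }
  d <- dim(a)
  feats <- matrix(a, d[1] * d[2] * d[3], d[4])     # nfeat x N
  logits <- params$projW %*% feats + params$projB
  list(feats = feats, logits = logits, probs = softmaxCols(logits),
       caches = caches, outDim = d)
}

# Mean cross-entropy loss and full gradients for a batch.
# Y: integer class indices (1-based), length N.
cnnLossGrad <- function(params, X, Y, spec) {
  fw <- cnnForwardCore(params, X, spec, keep = TRUE)
  N <- dim(X)[4]
  p <- fw$probs
  eps <- 1e-12
  loss <- -mean(log(p[cbind(Y, seq_len(N))] + eps))
  dZ <- p
  dZ[cbind(Y, seq_len(N))] <- dZ[cbind(Y, seq_len(N))] - 1
  dZ <- dZ / N
  grads <- list(conv = vector("list", length(params$conv)),
                projW = dZ %*% t(fw$feats), projB = rowSums(dZ))
  dFeats <- t(params$projW) %*% dZ
  da <- array(dFeats, c(fw$outDim))
  ci <- length(params$conv)
  for (li in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[li]]
    if (ly$type == "conv") {
      cache <- fw$caches[[li]]
      bk <- convBackward(da, cache$input, params$conv[[ci]]$W, ly$stride,
                         cache$fw, needInputGrad = li > 1L)
      grads$conv[[ci]] <- list(dW = bk$dW, db = bk$db)
      da <- bk$dX
      ci <- ci - 1L
    } else if (ly$type == "pool") {
      cache <- fw$caches[[li]]
      da <- poolBackward(da, cache$input, ly$kernel, ly$stride, cache$fw)
    } else if (ly$type == "relu") {
      da <- da * (fw$caches[[li]]$input > 0)
    }
  }
  list(loss = loss, grads = grads, probs = p)
}

# coerce patches (list of matrices, or array H x W x N / H x W x 1 x N) to
# the canonical 4-D tensor
asInputTensor <- function(x, inputSize) {
  if (is.list(x)) {
    x <- vapply(x, identity, matrix(0, inputSize, inputSize))
    dim(x) <- c(inputSize, inputSize, 1L, dim(x)[3])
  } else if (length(dim(x)) == 2L) {
    dim(x) <- c(dim(x), 1L, 1L)
  } else if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  }
  if (dim(x)[1] != inputSize || dim(x)[2] != inputSize)
    stop("patches must be ", inputSize, " x ", inputSize,
         ", got ", dim(x)[1], " x ", dim(x)[2])
  x
}

#' Forward propagation
#'
#' Runs the network on one or more patches and returns the class
#' probabilities (softmax of the projected logits; each column sums to 1)
#' together with the feature vectors entering the projection.
#'
#' @param model a [CNNModel-class].
#' @param patches a single matrix, a list of matrices, or an array
#'   (H, W, N) / (H, W, 1, N); spatial size must match the spec input size.
#' @return list with \code{probs} (classes x N, column-stochastic) and
#'   \code{features} (40 x N for the default spec).
#' @export
cnnForward <- function(model, patches) {
  stopifnot(is(model, "CNNModel"))
  X <- asInputTensor(patches, model@spec$inputSize)
  fw <- cnnForwardCore(model@params, X, model@spec)
  dimnames(fw$probs) <- list(model@classLevels, NULL)
  list(probs = fw$probs, features = fw$feats)
}

#' Extract the learned feature vector
#'
#' The CNN descriptor is the vector of activations entering the final
#' projection (40 values for the default architecture), identical to the
#' \code{features} element of [cnnForward()].
#'
#' @inheritParams cnnForward
#' @return numeric matrix, features x N (a plain vector for a single patch).
#' @export
cnnFeatures <- function(model, patches) {
  f <- cnnForward(model, patches)$features
  if (ncol(f) == 1L) drop(f) else f
}

#' Train the network with mini-batch SGD
#'
#' Minimizes mean cross-entropy with plain stochastic gradient descent.
#' Batches are sampled uniformly with replacement; everything downstream of
#' the seed (initialization included, unless a warm-start model is given) is
#' deterministic.
#'
#' @param patches training patches (same forms as in [cnnForward()]).
#' @param labels factor or character vector with exactly two classes present.
#' @param spec network spec (default [buildCNNSpec()]).
#' @param learningRate SGD step size (default 0.01).
#' @param batchSize mini-batch size (default 32).
#' @param maxIterations number of SGD iterations (default 1770).
#' @param seed integer seed (default 0).
#' @param model optional warm-start [CNNModel-class] (overrides \code{spec}).
#' @return a trained [CNNModel-class]; \code{model@trace} holds the
#'   per-iteration loss and mini-batch accuracy.
#' @export
trainCNN <- function(patches, labels, spec = buildCNNSpec(),
                     learningRate = 0.01, batchSize = 32L,
                     maxIterations = 1770L, seed = 0L, model = NULL) {
  if (learningRate <= 0 || batchSize < 1L || maxIterations < 1L)
    stop("hyperparameters must be positive")
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L)
    stop("training needs exactly 2 classes present, got ", nlevels(labels))
  if (is.null(model)) model <- initCNN(spec, seed = seed)
  spec <- model@spec
  X <- asInputTensor(patches, spec$inputSize)
  N <- dim(X)[4]
  if (length(labels) != N) stop("labels must match the number of patches")
  y <- as.integer(labels)
  params <- model@params
  tr <- matrix(0, maxIterations, 3)
  withSeed(seed + 1L, {
    for (it in seq_len(maxIterations)) {
      b <- sample.int(N, min(batchSize, N), replace = batchSize > N)
      lg <- cnnLossGrad(params, X[, , , b, drop = FALSE], y[b], spec)
      for (ci in seq_along(params$conv)) {
        params$conv[[ci]]$W <- params$conv[[ci]]$W - learningRate * lg$grads$conv[[ci]]$dW
        params$conv[[ci]]$b <- params$conv[[ci]]$b - learningRate * lg$grads$conv[[ci]]$db
      }
      params$projW <- params$projW - learningRate * lg$grads$projW
      params$projB <- params$projB - learningRate * lg$grads$projB
      pred <- max.col(t(lg$probs))
      tr[it, ] <- c(it, lg$loss, mean(pred == y[b]))
    }
  })
  new("CNNModel", spec = spec, params = params,
      trace = data.frame(iteration = as.integer(tr[, 1]), loss = tr[, 2],
                         accuracy = tr[, 3]),
      classLevels = levels(labels))
}

#' Predict class labels
#'
#' @param model a trained [CNNModel-class].
#' @param patches patches as in [cnnForward()].
#' @return factor of predicted labels.
#' @export
cnnPredict <- function(model, patches) {
  p <- cnnForward(model, patches)$probs
  factor(model@classLevels[max.col(t(p))], levels = model@classLevels)
}

#' Save / load network parameters
#'
#' Parameters, spec and training trace are serialized with a format version
#' field so archives remain readable across package versions.
#'
#' @param model a [CNNModel-class].
#' @param path file path for the parameter archive (.rds).
#' @return \code{saveCNN} invisibly returns \code{path}; \code{loadCNN}
#'   returns the restored [CNNModel-class].
#' @export
saveCNN <- function(model, path) {
  stopifnot(is(model, "CNNModel"))
  saveRDS(list(format = 1L, spec = model@spec, params = model@params,
               trace = model@trace, classLevels = model@classLevels), path)
  invisible(path)
}

#' @rdname saveCNN
#' @export
loadCNN <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, 1L)) stop("unsupported CNN archive format")
  new("CNNModel", spec = obj$spec, params = obj$params, trace = obj$trace,
      classLevels = obj$classLevels)
}
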