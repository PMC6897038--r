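#' @import methods
#' @importFrom stats rnorm runif sd var predict
#' @importFrom Rcpp sourceCpp
#' @useDynLib noduleFusion, .registration = TRUE
NULL

#' Configuration for the synthetic patch generator
#'
#' Holds the study conditions emulated by [generateDataset()]: class counts
#' (defaults 467 nodule / 131 non-nodule five-slice stacks), patch geometry,
#' additive Gaussian noise level and the range of nodule sizes.
#'
#' @slot nNodule number of nodule stacks (>= 1).
#' @slot nNonNodule number of non-nodule stacks (>= 1).
#' @slot patchSize patch side length in pixels (>= 16).
#' @slot noiseSd standard deviation of additive Gaussian noise, in intensity
#'   units on the \[0, 1\] scale (>= 0).
#' @slot noduleRadiusRange two increasing positive values: range (pixels) the
#'   Gaussian-blob radius is drawn from, uniformly.
#' @slot seed integer seed; the generator is bit-reproducible given the seed.
#'
#' @seealso [synthConfig()] for the user-facing constructor.
#' @export
setClass("SynthConfig",
  representation(
    nNodule = "integer",
    nNonNodule = "integer",
    patchSize = "integer",
    noiseSd = "numeric",
    noduleRadiusRange = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (length(object@nNodule) != 1L || is.na(object@nNodule) || object@nNodule < 1L)
    msg <- c(msg, "nNodule must be a single integer >= 1")
  if (length(object@nNonNodule) != 1L || is.na(object@nNonNodule) || object@nNonNodule < 1L)
    msg <- c(msg, "nNonNodule must be a single integer >= 1")
  if (length(object@patchSize) != 1L || is.na(object@patchSize) || object@patchSize < 16L)
    msg <- c(msg, "patchSize must be a single integer >= 16")
  if (length(object@noiseSd) != 1L || is.na(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single value >= 0")
  if (length(object@noduleRadiusRange) != 2L || any(is.na(object@noduleRadiusRange)) ||
      any(object@noduleRadiusRange <= 0) || diff(object@noduleRadiusRange) < 0)
    msg <- c(msg, "noduleRadiusRange must be two increasing positive values")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' A set of labelled five-slice patch stacks
#'
#' The unit of data in the pipeline: each sample is a stack of five ordered
#' square grayscale slices (p2, p1, n, n1, n2; the center slice, index 3, is
#' the region of interest) with a class label and LIDC-style manifest
#' metadata (patientid, noduleid, slicenumber, zposition, diameter, label).
#'
#' @slot stacks numeric array of dimension \code{c(patchSize, patchSize, 5,
#'   n)} with intensities in \[0, 1\].
#' @slot manifest \code{data.frame} with one row per stack and columns
#'   patientid, noduleid, slicenumber, zposition, diameter, label.
#' @slot seed integer seed the set was generated with (NA when read from
#'   disk).
#'
#' @export
setClass("NoduleStackSet",
  representation(
    stacks = "array",
    manifest = "data.frame",
    seed = "integer"
  )
)

setValidity("NoduleStackSet", function(object) {
  d <- dim(object@stacks)
  msg <- character()
  if (length(d) != 4L)
    return("stacks must be a 4-D array (rows, cols, 5 slices, samples)")
  if (d[3] != 5L)
    msg <- c(msg, "each stack must have exactly 5 slices")
  if (d[1] != d[2])
    msg <- c(msg, "patches must be square")
  if (nrow(object@manifest) != d[4])
    msg <- c(msg, "manifest must have one row per stack")
  need <- c("patientid", "noduleid", "slicenumber", "zposition", "diameter", "label")
  if (!all(need %in% names(object@manifest)))
    msg <- c(msg, paste("manifest must have columns:", paste(need, collapse = ", ")))
  else if (!all(object@manifest$label %in% c("nodule", "nonnodule")))
    msg <- c(msg, "labels must be 'nodule' or 'nonnodule'")
  rng <- range(object@stacks)
  if (rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "patch intensities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Confusion counts in the published-table layout
#'
#' The positive class is \emph{nodule}. The layout follows the convention of
#' the published confusion matrices: row one holds the true nodules, row two
#' the true non-nodules, so
#' \describe{
#'   \item{tp}{nodules predicted nodule (row 1, col 1),}
#'   \item{fp}{nodules predicted non-nodule (row 1, col 2 -- a \emph{missed
#'     nodule}, unlike the usual meaning of FP),}
#'   \item{fn}{non-nodules predicted nodule (row 2, col 1),}
#'   \item{tn}{non-nodules predicted non-nodule (row 2, col 2).}
#' }
#' Under this layout \code{tp + fp} is the number of true nodules and
#' \code{fn + tn} the number of true non-nodules. [metricsPanel()] reports
#' the metric panel with the formulas that reproduce the published values,
#' plus standard-convention aliases.
#'
#' @slot tp,fp,fn,tn non-negative integer counts as above.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", fn = "integer", tn = "integer")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4L || any(is.na(v))) return("all four counts must be single integers")
  if (any(v < 0L)) return("counts must be non-negative")
  TRUE
})

#' A small trainable convolutional network
#'
#' Architecture, parameters and training trace of the 9-layer network used as
#' the learned feature extractor: forward propagation maps a 50 x 50 x 1
#' patch to 1 x 1 x 2 class scores, and the 40 activations entering the final
#' projection are the CNN feature vector.
#'
#' @slot spec list describing the layer sequence (see [buildCNNSpec()]).
#' @slot params list of per-layer weight arrays/biases plus the projection.
#' @slot trace \code{data.frame} with one row per SGD iteration (iteration,
#'   loss, accuracy on the mini-batch); empty for untrained models.
#' @slot classLevels character vector of the two class labels, in the order
#'   of the output units.
#' @export
setClass("CNNModel",
  representation(
    spec = "list",
    params = "list",
    trace = "data.frame",
    classLevels = "character"
  )
)

#' Five-split validation scheme
#'
#' The evaluation protocol: five independent stratified train/test partitions
#' at train fractions 10, 20, 30, 40 and 50 percent; held-out predictions
#' from the five splits are pooled into a single confusion matrix per
#' feature-set/classifier combination.
#'
#' @slot trainFractions ordered numeric vector of train percentages in
#'   (0, 100).
#' @slot stratified logical; splits preserve class proportions.
#' @slot seed integer seed driving all split randomness.
#' @export
setClass("SplitScheme",
  representation(trainFractions = "numeric", stratified = "logical", seed = "integer")
)

setValidity("SplitScheme", function(object) {
  f <- object@trainFractions
  if (!length(f) || any(is.na(f)) || any(f <= 0) || any(f >= 100))
    return("trainFractions must lie strictly between 0 and 100")
  if (length(object@stratified) != 1L || is.na(object@stratified))
    return("stratified must be TRUE or FALSE")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nNodule, "nodule +", object@nNonNodule,
      "non-nodule stacks,", object@patchSize, "px patches\n")
  cat("  noise sd:", object@noiseSd,
      " blob radius: [", object@noduleRadiusRange[1], ",",
      object@noduleRadiusRange[2], "] px  seed:", object@seed, "\n")
})

setMethod("show", "NoduleStackSet", function(object) {
  d <- dim(object@stacks)
  tab <- table(object@manifest$label)
  cat("NoduleStackSet:", d[4], "stacks of 5 slices,", d[1], "x", d[2], "px\n")
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (rows = truth, published layout; positive = nodule)\n")
  m <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2, 2, byrow = TRUE,
              dimnames = list(c("nodule", "nonnodule"),
                              c("pred nodule", "pred nonnodule")))
  print(m)
})

setMethod("show", "CNNModel", function(object) {
  tr <- shapeTrace(object@spec)
  cat("CNNModel:", length(object@spec$layers), "feature layers + projection/softmax\n")
  cat("  spatial trace:", paste(tr, collapse = " -> "), "\n")
  if (nrow(object@trace))
    cat("  trained:", nrow(object@trace), "iterations, final batch loss",
        signif(object@trace$loss[nrow(object@trace)], 4), "\n")
  else cat("  untrained\n")
})

setMethod("show", "SplitScheme", function(object) {
  cat("SplitScheme: train fractions",
      paste0(object@trainFractions, "%", collapse = ", "),
      if (object@stratified) "(stratified)" else "(unstratified)",
      "seed", object@seed, "\n")
})

#' @describeIn SynthConfig-class accessor for the number of stacks per class.
#' @param x a \code{SynthConfig} or \code{NoduleStackSet}.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

setMethod("classCounts", "SynthConfig", function(x)
  c(nodule = x@nNodule, nonnodule = x@nNonNodule))

setMethod("classCounts", "NoduleStackSet", function(x) {
  tab <- table(factor(x@manifest$label, levels = c("nodule", "nonnodule")))
  c(nodule = unname(tab["nodule"]), nonnodule = unname(tab["nonnodule"]))
})

#' Manifest accessor
#' @param x a \code{NoduleStackSet}.
#' @return the manifest \code{data.frame}.
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname manifest
setMethod("manifest", "NoduleStackSet", function(x) x@manifest)

#' Stack labels accessor
#' @param x a \code{NoduleStackSet}.
#' @return factor of labels with levels nodule, nonnodule.
#' @export
setGeneric("stackLabels", function(x) standardGeneric("stackLabels"))

#' @rdname stackLabels
setMethod("stackLabels", "NoduleStackSet", function(x)
  factor(x@manifest$label, levels = c("nodule", "nonnodule")))

#' Extract one slice across all stacks
#'
#' @param x a \code{NoduleStackSet}.
#' @param slice slice index 1..5 (3 = center) or one of "p2", "p1", "n",
#'   "n1", "n2".
#' @return numeric array (size, size, n).
#' @export
setGeneric("getSlice", function(x, slice = 3L) standardGeneric("getSlice"))

#' @rdname getSlice
setMethod("getSlice", "NoduleStackSet", function(x, slice = 3L) {
  if (is.character(slice))
    slice <- match(slice, c("p2", "p1", "n", "n1", "n2"))
  if (is.na(slice) || slice < 1L || slice > 5L)
    stop("slice must be 1..5 or one of p2, p1, n, n1, n2")
  x@stacks[, , slice, , drop = FALSE][, , 1L, , drop = TRUE]
})

#' Number of stacks
#' @param x a \code{NoduleStackSet}.
#' @export
setMethod("length", "NoduleStackSet", function(x) dim(x@stacks)[4])
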