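CANONICAL_DESCRIPTORS <- c("HOG", "ExHOG", "CNN", "LBP")

#' Extract descriptor features from a patch dataset
#'
#' Runs the requested extractors on every sample and returns the feature
#' table as a \linkS4class{SummarizedExperiment}: one assay
#' \code{features} (features x samples), \code{rowData} recording which
#' descriptor each row belongs to, and \code{colData} carrying the manifest
#' fields and label. Rows are ordered by descriptor in the canonical fusion
#' order HOG, ExHOG, CNN, LBP.
#'
#' HOG, ExHOG and LBP work on patches resized to \code{descriptorSize}
#' (default 28); the CNN works on \code{cnnSize} (default 50). With
#' \code{slices = "center"} each stack contributes one sample (its region-of-
#' interest slice); with \code{slices = "all"} each of the five slices
#' becomes a sample carrying the stack's label.
#'
#' @param dataset a [NoduleStackSet-class].
#' @param descriptors subset of \code{c("HOG", "ExHOG", "CNN", "LBP")}.
#' @param cnnModel a trained [CNNModel-class]; required when "CNN" is
#'   requested.
#' @param slices "center" (default) or "all".
#' @param descriptorSize working size for the hand-crafted descriptors.
#' @param cnnSize working size for the network input.
#' @return a \code{SummarizedExperiment}.
#' @export
extractFeatures <- function(dataset,
                            descriptors = c("HOG", "ExHOG", "CNN", "LBP"),
                            cnnModel = NULL, slices = c("center", "all"),
                            descriptorSize = 28L, cnnSize = 50L) {
  stopifnot(is(dataset, "NoduleStackSet"))
  slices <- match.arg(slices)
  descriptors <- match.arg(descriptors, CANONICAL_DESCRIPTORS, several.ok = TRUE)
  descriptors <- CANONICAL_DESCRIPTORS[CANONICAL_DESCRIPTORS %in% descriptors]
  if ("CNN" %in% descriptors && is.null(cnnModel))
    stop("a trained cnnModel is required to extract CNN features")

  man <- manifest(dataset)
  sliceIdx <- if (slices == "center") 3L else 1:5
  nStack <- length(dataset)
  sampleStack <- rep(seq_len(nStack), each = length(sliceIdx))
  sampleSlice <- rep(sliceIdx, times = nStack)
  n <- length(sampleStack)

  blocks <- list()
  for (d in descriptors) {
    len <- descriptorLengths()[[d]]
    m <- matrix(0, len, n)
    if (d == "CNN") {
      arr <- array(0, c(cnnSize, cnnSize, 1L, n))
      for (s in seq_len(n))
        arr[, , 1L, s] <- resizePatch(
          dataset@stacks[, , sampleSlice[s], sampleStack[s]], cnnSize)
      # forward in fixed-size chunks to bound the im2col working memory
      chunk <- 32L
      for (from in seq(1L, n, by = chunk)) {
        to <- min(from + chunk - 1L, n)
        m[, from:to] <- cnnForward(cnnModel,
                                   arr[, , , from:to, drop = FALSE])$features
      }
    } else {
      for (s in seq_len(n)) {
        p28 <- resizePatch(dataset@stacks[, , sampleSlice[s], sampleStack[s]],
                           descriptorSize)
        m[, s] <- switch(d,
          HOG = hogDescriptor(p28),
          ExHOG = exhogDescriptor(p28),
          LBP = lbpDescriptor(p28))
      }
    }
    rownames(m) <- sprintf("%s_f%04d", d, seq_len(len) - 1L)
    blocks[[d]] <- m
  }
  feat <- do.call(rbind, blocks)
  cd <- man[sampleStack, , drop = FALSE]
  cd$slice <- c("p2", "p1", "n", "n1", "n2")[sampleSlice]
  cd$stack <- sampleStack
  rownames(cd) <- sprintf("sample%04d", seq_len(n))
  colnames(feat) <- rownames(cd)
  rd <- S4Vectors::DataFrame(
    descriptor = rep(descriptors, vapply(blocks, nrow, 0L)),
    row.names = rownames(feat))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat), rowData = rd,
    colData = S4Vectors::DataFrame(cd))
}

#' Fuse descriptors into a hybrid feature matrix
#'
#' Concatenates the requested descriptor blocks in the canonical order HOG,
#' ExHOG, CNN, LBP (restricted to \code{featureSet}); the fused length is the
#' sum of the member lengths (e.g. HOG + CNN = 1296 + 40 = 1336). A singleton
#' set returns that descriptor's block unchanged.
#'
#' @param features a \code{SummarizedExperiment} from [extractFeatures()], or
#'   a named list of per-descriptor vectors/matrices for a single sample set.
#' @param featureSet non-empty subset of \code{c("HOG","ExHOG","CNN","LBP")}.
#' @return numeric matrix, fused features x samples (or a vector when the
#'   input was a list of vectors).
#' @export
fuseFeatures <- function(features, featureSet) {
  if (!length(featureSet)) stop("featureSet must be non-empty")
  bad <- setdiff(featureSet, CANONICAL_DESCRIPTORS)
  if (length(bad)) stop("unknown descriptor(s): ", paste(bad, collapse = ", "))
  featureSet <- CANONICAL_DESCRIPTORS[CANONICAL_DESCRIPTORS %in% featureSet]
  if (is.list(features) && !is(features, "SummarizedExperiment")) {
    missing <- setdiff(featureSet, names(features))
    if (length(missing))
      stop("missing descriptor(s): ", paste(missing, collapse = ", "))
    vec <- all(vapply(features[featureSet], is.vector, TRUE))
    out <- do.call(rbind, lapply(features[featureSet], as.matrix))
    return(if (vec && ncol(out) == 1L) drop(out) else out)
  }
  rd <- SummarizedExperiment::rowData(features)
  missing <- setdiff(featureSet, unique(rd$descriptor))
  if (length(missing))
    stop("missing descriptor(s): ", paste(missing, collapse = ", "))
  keep <- unlist(lapply(featureSet, function(d) which(rd$descriptor == d)))
  SummarizedExperiment::assay(features, "features")[keep, , drop = FALSE]
}

#' Write a feature table to CSV
#'
#' One row per sample: sample id, label, slice, then the feature columns
#' (named \code{<descriptor>_f<i>}).
#'
#' @param features a \code{SummarizedExperiment} from [extractFeatures()].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeFeatureCSV <- function(features, path) {
  m <- t(SummarizedExperiment::assay(features, "features"))
  cd <- SummarizedExperiment::colData(features)
  df <- data.frame(sample = rownames(cd), label = cd$label,
                   slice = cd$slice, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
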