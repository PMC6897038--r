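#' Build confusion counts from label vectors
#'
#' Tallies predictions into the published-table layout (see
#' [ConfusionCounts-class]): the positive class is \emph{nodule}; row one of
#' the matrix holds the true nodules (correctly recovered, missed), row two
#' the true non-nodules (missed, correctly rejected).
#'
#' @param truth,predicted equal-length vectors/factors over
#'   \{"nodule", "nonnodule"\}.
#' @return a [ConfusionCounts-class].
#' @examples
#' confusionCounts(rep(c("nodule", "nonnodule"), c(5, 3)),
#'                 rep(c("nodule", "nonnodule"), c(5, 3)))
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  ok <- c("nodule", "nonnodule")
  bad <- setdiff(unique(c(truth, predicted)), ok)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  new("ConfusionCounts",
      tp = sum(truth == "nodule" & predicted == "nodule"),
      fp = sum(truth == "nodule" & predicted == "nonnodule"),
      fn = sum(truth == "nonnodule" & predicted == "nodule"),
      tn = sum(truth == "nonnodule" & predicted == "nonnodule"))
}

#' Confusion counts from the four cells
#'
#' @param tp,fp,fn,tn counts in the published layout (see
#'   [ConfusionCounts-class]).
#' @return a [ConfusionCounts-class].
#' @export
confusionFromCounts <- function(tp, fp, fn, tn) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

#' Full metric panel from confusion counts
#'
#' Computes the evaluation panel, in percent, with the exact arithmetic that
#' reproduces the published tables under their confusion layout (tp+fp = true
#' nodules, fn+tn = true non-nodules):
#' \describe{
#'   \item{accuracy}{(tp + tn) / n}
#'   \item{sensitivity, recall}{tp / (tp + fp) -- fraction of true nodules
#'     recovered}
#'   \item{specificity}{tn / (fp + tn)}
#'   \item{precision}{tp / (tp + fn) -- fraction of predicted nodules that
#'     are nodules}
#'   \item{fscore}{harmonic mean 2PR / (P + R); defined as 0 when
#'     P + R = 0}
#'   \item{ppv}{tp / (tp + fp) (the arithmetic the published PPV values
#'     follow; equal to sensitivity under this layout)}
#'   \item{npv}{tn / (tn + fn) (the arithmetic the published NPV values
#'     follow)}
#'   \item{kappa}{Cohen's chance-corrected agreement
#'     (p_a - p_e) / (1 - p_e), with p_e from the row/column marginals}
#' }
#' Standard-convention aliases computed with the textbook definitions
#' (positive class nodule, so standard FN = missed nodules = this layout's
#' \code{fp}) are appended as \code{sensitivityStd = tp/(tp+fp)},
#' \code{specificityStd = tn/(tn+fn)}, \code{ppvStd = tp/(tp+fn)},
#' \code{npvStd = tn/(tn+fp)}.
#'
#' Any metric with a zero denominator is reported as 0 and named in the
#' \code{flags} attribute.
#'
#' @param counts a [ConfusionCounts-class].
#' @return one-row \code{data.frame} of percentages in \[0, 100\], with
#'   attribute \code{flags} (character vector of zero-denominator metrics).
#' @examples
#' metricsPanel(confusionFromCounts(452, 15, 13, 118))$accuracy
#' @export
metricsPanel <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  validObject(counts)
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  n <- tp + fp + fn + tn
  if (n <= 0L) stop("empty confusion matrix")
  flags <- character()
  ratio <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); 0 } else num / den
  }
  accuracy <- (tp + tn) / n
  sensitivity <- ratio(tp, tp + fp, "sensitivity")
  specificity <- ratio(tn, fp + tn, "specificity")
  precision <- ratio(tp, tp + fn, "precision")
  recall <- sensitivity
  fscore <- if (precision + recall == 0) {
    flags <- c(flags, "fscore"); 0
  } else 2 * precision * recall / (precision + recall)
  ppv <- ratio(tp, tp + fp, "ppv")
  npv <- ratio(tn, tn + fn, "npv")
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) { flags <- c(flags, "kappa"); 0 }
           else (accuracy - pe) / (1 - pe)
  out <- data.frame(
    accuracy = 100 * accuracy, sensitivity = 100 * sensitivity,
    specificity = 100 * specificity, kappa = 100 * kappa,
    precision = 100 * precision, recall = 100 * recall,
    fscore = 100 * fscore, ppv = 100 * ppv, npv = 100 * npv,
    sensitivityStd = 100 * ratio(tp, tp + fp, "sensitivityStd"),
    specificityStd = 100 * ratio(tn, tn + fn, "specificityStd"),
    ppvStd = 100 * ratio(tp, tp + fn, "ppvStd"),
    npvStd = 100 * ratio(tn, tn + fp, "npvStd"))
  attr(out, "flags") <- unique(flags)
  out
}
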