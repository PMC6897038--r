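#' Load a grayscale patch from disk
#'
#' Reads an 8- or 16-bit PNG or TIFF image as a numeric matrix with
#' intensities on the \[0, 1\] scale (integer sample values are divided by the
#' dtype maximum, so an 8-bit PNG of all 255 loads as all 1.0 and a constant
#' zero image as all 0.0). Multi-channel images are rejected.
#'
#' @param path file path.
#' @param format image format; inferred from the file extension by default.
#' @return numeric matrix (rows x cols) in \[0, 1\].
#' @seealso [resizePatch()]
#' @export
loadPatch <- function(path, format = c("auto", "png", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read patch file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, png = "png", tif = , tiff = "tiff",
                     stop("unsupported patch format '", ext, "' for ", path))
  }
  img <- tryCatch(EBImage::readImage(path, type = format),
                  error = function(e) stop("failed to read ", path, ": ",
                                           conditionMessage(e)))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L && dim(dat)[3] == 1L) dat <- dat[, , 1L]
  if (length(dim(dat)) != 2L)
    stop("patch must be a single-channel 2-D image: ", path)
  # EBImage stores images x-major; transpose to row/col matrix orientation
  clip01(t(dat))
}

#' Write a patch as an 8-bit grayscale PNG
#'
#' Inverse of [loadPatch()] up to 8-bit quantization (round-trip error at
#' most 1/255 per pixel).
#'
#' @param patch numeric matrix in \[0, 1\].
#' @param path output file path (.png).
#' @return invisibly, \code{path}.
#' @export
writePatch <- function(patch, path) {
  if (!is.matrix(patch) || !is.numeric(patch)) stop("patch must be a numeric matrix")
  EBImage::writeImage(EBImage::Image(t(clip01(patch))), path,
                      type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Resize a patch with bilinear interpolation
#'
#' Each descriptor declares its own working size (28 x 28 for the gradient
#' and texture descriptors, 50 x 50 for the network); this is the shared
#' resampling step. Constant patches are preserved exactly and output values
#' never leave the input range (bilinear interpolation is a convex
#' combination of input pixels). A same-size call returns the input
#' unchanged.
#'
#' @param patch numeric matrix in \[0, 1\].
#' @param target output side length in pixels (>= 2).
#' @return a \code{target} x \code{target} numeric matrix.
#' @examples
#' p <- matrix(runif(2500), 50, 50)
#' dim(resizePatch(p, 28))
#' @export
resizePatch <- function(patch, target) {
  if (!is.matrix(patch) || !is.numeric(patch)) stop("patch must be a numeric matrix")
  target <- as.integer(target)
  if (is.na(target) || target < 2L) stop("target must be an integer >= 2")
  if (nrow(patch) == target && ncol(patch) == target) return(patch)
  out <- EBImage::resize(EBImage::Image(t(patch)), w = target, h = target,
                         filter = "bilinear")
  t(EBImage::imageData(out))
}
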