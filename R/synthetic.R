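#' Create a synthetic-data configuration
#'
#' Constructor for [SynthConfig-class]. The defaults reproduce the study
#' conditions emulated throughout the package: 467 nodule and 131 non-nodule
#' five-slice stacks of 50 x 50 pixel patches.
#'
#' @param nNodule number of nodule stacks (default 467).
#' @param nNonNodule number of non-nodule stacks (default 131).
#' @param patchSize patch side in pixels (default 50, minimum 16).
#' @param noiseSd additive Gaussian noise sd on the \[0,1\] intensity scale
#'   (default 0.05).
#' @param noduleRadiusRange range (pixels) the nodule blob radius is drawn
#'   from (default \code{c(3, 8)}).
#' @param seed integer seed (default 0).
#' @return a validated \code{SynthConfig}.
#' @examples
#' cfg <- synthConfig(nNodule = 10, nNonNodule = 5, seed = 1)
#' classCounts(cfg)
#' @export
synthConfig <- function(nNodule = 467L, nNonNodule = 131L, patchSize = 50L,
                        noiseSd = 0.05, noduleRadiusRange = c(3, 8),
                        seed = 0L) {
  new("SynthConfig",
      nNodule = as.integer(nNodule), nNonNodule = as.integer(nNonNodule),
      patchSize = as.integer(patchSize), noiseSd = as.numeric(noiseSd),
      noduleRadiusRange = as.numeric(noduleRadiusRange),
      seed = as.integer(seed))
}

# One anisotropic Gaussian blob on an size x size grid.
# center: length-2 (row, col); sigma: length-2 axis radii; angle: rotation.
gaussianBlob <- function(size, center, sigma, angle, amplitude) {
  co <- cos(angle); si <- sin(angle)
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  dr <- g$r - center[1]; dc <- g$c - center[2]
  u <- co * dr + si * dc
  v <- -si * dr + co * dc
  z <- amplitude * exp(-0.5 * ((u / sigma[1])^2 + (v / sigma[2])^2))
  matrix(z, size, size)
}

# Vessel-like bright ridge: a line through a random point, Gaussian profile
# across the line.
ridgePatch <- function(size, through, angle, width, amplitude) {
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  # signed distance to the line through `through` with direction `angle`
  d <- -sin(angle) * (g$r - through[1]) + cos(angle) * (g$c - through[2])
  matrix(amplitude * exp(-0.5 * (d / width)^2), size, size)
}

#' Generate a labelled synthetic patch dataset
#'
#' Emulates LIDC-style nodule / non-nodule patch stacks so the whole pipeline
#' can be exercised without the real CT data. Nodule stacks contain a bright,
#' roughly round or oval Gaussian blob (amplitude 0.5--0.9 over a 0.2
#' background, radius drawn from \code{noduleRadiusRange}, center jittered by
#' up to 10\% of the patch) whose intensity peaks on the center slice and
#' decays with slice offset by factors (1, 0.7, 0.4). Non-nodule stacks are
#' either an elongated vessel-like ridge (50\%) or flat background noise
#' (50\%). Additive Gaussian noise is applied per slice and intensities are
#' clipped to \[0, 1\]. Output is bit-identical for a fixed configuration
#' (including its seed).
#'
#' @param config a [SynthConfig-class], e.g. from [synthConfig()].
#' @return a [NoduleStackSet-class] whose manifest carries synthetic
#'   patientid, noduleid, slicenumber, zposition, diameter and label fields.
#' @examples
#' ds <- generateDataset(synthConfig(nNodule = 6, nNonNodule = 4, seed = 1))
#' length(ds)
#' classCounts(ds)
#' @export
generateDataset <- function(config) {
  if (!is(config, "SynthConfig")) stop("config must be a SynthConfig")
  validObject(config)
  n <- config@nNodule + config@nNonNodule
  size <- config@patchSize
  decay <- c(0.4, 0.7, 1, 0.7, 0.4)   # slice multipliers p2, p1, n, n1, n2
  background <- 0.2

  withSeed(config@seed, {
    stacks <- array(0, c(size, size, 5L, n))
    labels <- c(rep("nodule", config@nNodule), rep("nonnodule", config@nNonNodule))
    diam <- numeric(n)
    for (i in seq_len(n)) {
      if (labels[i] == "nodule") {
        amp <- runif(1, 0.5, 0.9)
        radius <- runif(1, config@noduleRadiusRange[1], config@noduleRadiusRange[2])
        aspect <- runif(1, 0.75, 1.3)
        angle <- runif(1, 0, pi)
        center <- (size + 1) / 2 + runif(2, -0.1, 0.1) * size
        sig <- radius * c(sqrt(aspect), 1 / sqrt(aspect))
        blob <- gaussianBlob(size, center, sig, angle, amp)
        diam[i] <- 2 * radius
        for (k in 1:5)
          stacks[, , k, i] <- background + decay[k] * blob +
            rnorm(size * size, 0, config@noiseSd)
      } else {
        ridge <- runif(1) < 0.5
        diam[i] <- 0
        if (ridge) {
          amp <- runif(1, 0.5, 0.9)
          width <- runif(1, 1.5, 3)
          angle <- runif(1, 0, pi)
          through <- runif(2, 0.25, 0.75) * size
          base <- ridgePatch(size, through, angle, width, amp)
        } else {
          base <- matrix(0, size, size)
        }
        for (k in 1:5)
          stacks[, , k, i] <- background + base +
            rnorm(size * size, 0, config@noiseSd)
      }
    }
    stacks <- clip01(stacks)
    sliceno <- sample(20:120, n, replace = TRUE)
    man <- data.frame(
      patientid = sprintf("SYN-%04d", seq_len(n)),
      noduleid = sprintf("N%04d", seq_len(n)),
      slicenumber = sliceno,
      zposition = round(-100 - 2.5 * sliceno, 2),
      diameter = round(diam, 2),
      label = labels,
      stringsAsFactors = FALSE
    )
    new("NoduleStackSet", stacks = stacks, manifest = man, seed = config@seed)
  })
}

#' Write a dataset to disk as PNG slices plus a manifest CSV
#'
#' Each slice is written as an 8-bit grayscale PNG named
#' \code{<patientid>_<noduleid>_s<k>.png} (k = 1..5); the manifest CSV has the
#' header \code{patientid,noduleid,slicenumber,zposition,diameter,label}. A
#' \code{runinfo.txt} records the generator seed and a hash of the manifest
#' for reproducibility checks.
#'
#' @param dataset a [NoduleStackSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "NoduleStackSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- manifest(dataset)
  for (i in seq_len(nrow(man))) {
    for (k in 1:5) {
      f <- file.path(dir, sprintf("%s_%s_s%d.png", man$patientid[i], man$noduleid[i], k))
      writePatch(dataset@stacks[, , k, i], f)
    }
  }
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE, quote = FALSE)
  info <- c(
    sprintf("seed: %d", dataset@seed),
    sprintf("manifest_md5: %s", unname(tools::md5sum(manPath))),
    sprintf("n_stacks: %d", nrow(man))
  )
  writeLines(info, file.path(dir, "runinfo.txt"))
  invisible(manPath)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir directory containing \code{manifest.csv} and the slice PNGs.
#' @return a [NoduleStackSet-class]. Intensities are re-quantized by the
#'   8-bit round trip (max abs error 1/255 per pixel).
#' @export
readDataset <- function(dir) {
  manPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manPath)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(manPath, stringsAsFactors = FALSE)
  n <- nrow(man)
  if (!n) stop("empty manifest in ", dir)
  first <- loadPatch(file.path(dir, sprintf("%s_%s_s1.png", man$patientid[1], man$noduleid[1])))
  size <- nrow(first)
  stacks <- array(0, c(size, size, 5L, n))
  for (i in seq_len(n)) {
    for (k in 1:5) {
      f <- file.path(dir, sprintf("%s_%s_s%d.png", man$patientid[i], man$noduleid[i], k))
      stacks[, , k, i] <- loadPatch(f)
    }
  }
  new("NoduleStackSet", stacks = stacks, manifest = man, seed = NA_integer_)
}
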