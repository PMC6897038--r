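# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code does not disturb user sessions.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# md5 of a character scalar (config hashes embedded in run-info files)
hashString <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

assertSquarePatch <- function(patch, minSize = 3L, what = "patch") {
  if (!is.matrix(patch) || !is.numeric(patch))
    stop(what, " must be a numeric matrix")
  if (nrow(patch) != ncol(patch))
    stop(what, " must be square, got ", nrow(patch), " x ", ncol(patch))
  if (nrow(patch) < minSize)
    stop(what, " must be at least ", minSize, " x ", minSize)
  invisible(TRUE)
}
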