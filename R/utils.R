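# Internal helpers: seeded evaluation and seed fan-out.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' The pipeline fans one master seed out to its stages so each stage can be
#' re-run in isolation reproducibly: `stageSeed(master, i) =
#' (master * 10007 + i * 101) mod (2^31 - 1)`.
#'
#' @param master master integer seed.
#' @param stage stage index (>= 1) or stage name from
#'   `c("simulate", "preprocess", "features", "screening", "embedding",
#'   "classify")`.
#' @return a single integer seed below 2^31.
#' @export
stageSeed <- function(master, stage) {
  stages <- c("simulate", "preprocess", "features", "screening",
              "embedding", "classify")
  if (is.character(stage)) {
    stage <- match(stage, stages)
    if (is.na(stage)) stop("unknown stage name")
  }
  as.integer((as.numeric(master) * 10007 + stage * 101) %% 2147483647)
}

# Pearson-normalized zero-lag correlation used throughout; exported surface
# is xcorr() in preprocess-artifact.R.
.pearson <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
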