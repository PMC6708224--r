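# Internal helpers shared across the pipeline.

#' Derive a stage seed from a global seed
#'
#' A single run seed fans out to per-stage seeds through a fixed affine map
#' modulo the Mersenne prime 2^31 - 1, so any stage can be re-run in
#' isolation with a reproducible stream.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 0) or a known stage name.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage = 0L) {
  if (is.character(stage)) {
    stages <- c(simulate = 1L, measures = 2L, reduce = 3L,
                cluster = 4L, compare = 5L)
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stage <- stages[[stage]]
  }
  as.integer((as.numeric(seed) * 48271 + stage) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Apportion n into groups by proportions using largest remainders, so counts
# sum to n exactly.
apportion <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Random composition of integer total into k positive integer parts.
rand_composition <- function(total, k) {
  stopifnot(total >= k, k >= 1)
  if (k == 1) return(total)
  cuts <- sort(sample.int(total - 1, k - 1))
  diff(c(0, cuts, total))
}

# sample() that never falls into the length-1 "sample from 1:x" trap.
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
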