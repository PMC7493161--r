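#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats prcomp runif rnorm rexp var sd quantile uniroot predict
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
## afterwards so generators and trainers are pure functions of their seed.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Numerically stable log(sum(exp(x)))
logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Derive a child seed from a base seed; stays within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
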