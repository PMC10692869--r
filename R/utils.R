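#' @importFrom stats predict rnorm runif qnorm pnorm rbinom glm binomial
#'   quasibinomial plogis median sd aggregate
#' @importFrom utils read.table write.table head
#' @importFrom methods new validObject is slot
NULL

#' @keywords internal
.msg <- function(..., verbose = getOption("FPsieve.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[FPsieve] ", ...)
}

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so library code never perturbs the user's random stream.
#' @keywords internal
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and a stream index; keeps every
## internal random draw reproducible from one user-supplied seed while
## staying inside the 32-bit integer range.
#' @keywords internal
.childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + 7919L * as.numeric(index)) %% 2147483647)
}

## Truncated normal draws via inverse-CDF; a and b may be -Inf/Inf.
#' @keywords internal
.rtnorm <- function(n, mean, sd, a = -Inf, b = Inf) {
  lo <- pnorm(a, mean, sd)
  hi <- pnorm(b, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Canonical variant group key
#'
#' Builds the `chrom:pos:ref:alt` key used to tie together duplicate calls of
#' the same variant coming from different capture kits. All duplicate-aware
#' splitting operates on these keys.
#'
#' @param chrom,pos,ref,alt vectors of equal length (recycled as usual).
#' @return character vector of keys.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
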