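#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats p.adjust pt qnorm rnorm runif rbinom rnbinom rpois
#'   rmultinom prcomp cor mad median quantile var sd model.matrix relevel
#'   complete.cases
#' @importFrom utils read.delim write.table combn head
NULL

## Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so library functions never clobber user randomness.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

## Derive a named sub-seed from a base seed, kept inside 32-bit integer range.
subSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + as.numeric(offset)) %% .Machine$integer.max)
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
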