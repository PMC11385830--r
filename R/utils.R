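#' @importFrom stats median mad rnbinom rnorm runif rexp rbinom var sd cor
#'   pnorm pt pchisq qnorm quantile setNames p.adjust complete.cases
#' @importFrom utils head write.table read.table combn
NULL

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Dense numeric matrix from any count-matrix-like input (dgCMatrix or matrix).
as_dense <- function(x) {
  if (methods::is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0
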