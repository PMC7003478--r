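#' @useDynLib parcbundle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats approx rnorm runif setNames
NULL

# log(sum(exp(x))) with max subtraction; safe for -Inf entries
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards. Makes every generator reproducible
# without perturbing unrelated draws.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a sub-seed for an operation from a master seed, keeping results
# independent of how many draws other operations consume. Stays < 2^31.
deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

stopIfNot3 <- function(p, what = "point") {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (ncol(p) != 3) stop(what, " must have 3 columns")
  storage.mode(p) <- "double"
  p
}
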