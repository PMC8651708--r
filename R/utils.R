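#' @useDynLib tetrasel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate anova cor dist lm optimize prcomp
#'   rbinom rbeta rexp rnorm runif sd setNames var
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
# seed = NULL leaves the current stream untouched.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic child seed for replicate `counter` of a run seeded with `seed`,
# kept inside the 32-bit integer range. Used so that replicates are
# reproducible independently of execution order.
child_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729) %% 2147483647)
}

# Integer allocation of n among groups proportional to weights, by the
# largest-remainder (Hamilton) method. Ties broken by group order.
largest_remainder <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    take <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# sample() without the length-1 surprise
sample_ids <- function(x, size) {
  x[sample.int(length(x), size)]
}
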