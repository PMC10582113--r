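#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm quantile median sd var cov dnorm qchisq rWishart
#'   runif qnorm setNames plogis qlogis
#' @importFrom utils head
NULL

# Derive a reproducible child seed from a parent seed and an index, so that
# whole-community draws stay stable when one group's n changes. Kept < 2^31.
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 999983 * index) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Root-mean-square pooling of standard deviations (used when two baseline
# taxa are merged into one baseline role).
rms <- function(x) sqrt(mean(x^2))

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
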