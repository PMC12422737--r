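#' @keywords internal
"_PACKAGE"

# logistic link used everywhere; stats::plogis is numerically safe
logistic <- function(eta) stats::plogis(eta)

#' Evaluate code with a local RNG state
#'
#' Seeds the RNG, runs `expr`, and restores the caller's RNG state so that
#' package functions taking a `seed` argument never perturb the global
#' random stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a substream seed from a master seed and an index. Fixed splitting so
# that e.g. worm 3's trajectory does not change when more worms are added.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %%
               2147483629) + 1L
}

# strict local maxima of a numeric vector (interior points only)
count_modes <- function(y) {
  n <- length(y)
  if (n < 3L) return(as.integer(n >= 1L))
  sum(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
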