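#' @useDynLib scutes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif optim pnorm dnorm median quantile sd fft
#' @importFrom utils head tail
NULL

## Local, restorable RNG: every stochastic entry point takes an explicit
## seed and never perturbs the caller's .Random.seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

## angle between sign-free axes, degrees in [0, 90]
axis_angle <- function(a, b) {
  c <- abs(sum(unit(a) * unit(b)))
  acos(min(1, c)) * 180 / pi
}
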