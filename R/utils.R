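#' @importFrom stats approx cor prcomp predict rnorm runif sd smooth.spline var
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded helpers do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive n child seeds (< 2^31) from one master seed, reproducibly.
spawn_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Cumulative trapezoidal integral of y (vector or matrix columns) over x.
## Hot path of training; deliberately minimal.
cumtrapz <- function(x, y) {
  n <- length(x)
  dx <- x[-1] - x[-n]
  if (is.matrix(y)) {
    mid <- (y[-1, , drop = FALSE] + y[-n, , drop = FALSE]) * (dx / 2)
    rbind(0, apply(mid, 2, cumsum))
  } else {
    c(0, cumsum((y[-1] + y[-n]) * (dx / 2)))
  }
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
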