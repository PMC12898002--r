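#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif rbinom rpois qnorm pnorm dnorm quantile
#'   median sd var cor acf optim predict rexp aggregate setNames
#' @importFrom utils head tail write.csv read.csv combn
NULL

## Run `expr` under a temporary RNG state seeded with `seed`; restore the
## caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a child seed from a base seed and a stream index, staying within
## 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(k) * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

## sample moments used throughout (population-style, matching weighted variants)
moment_skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(NA_real_)
  mean((x - m)^3) / s^3
}

moment_kurtosis_excess <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(NA_real_)
  mean((x - m)^4) / s^4 - 3
}
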