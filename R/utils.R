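#' Derive a replicate-level seed from a root seed
#'
#' Deterministic splitmix-style mixing of a root seed and a counter so that any
#' replicate of a simulation can be regenerated in isolation. All arithmetic is
#' exact in double precision and the result stays below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param index non-negative integer counter (replicate number, bootstrap
#'   draw, ...).
#' @return a single integer seed.
#' @export
#' @examples
#' mix_seed(1, 1:3)
mix_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  x <- (as.numeric(seed) %% 2147483647) + (as.numeric(index) %% 2147483647) * 2654435761
  x <- x %% 2147483647
  x <- (x * 48271 + 12820163) %% 2147483647
  as.integer(x)
}

# run code under a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_finite_or_na <- function(x) is.na(x) | is.finite(x)

# p-value significance markers used in the regression tables
sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
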