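# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the Mersenne-Twister stream with `seed`, evaluates `expr`, and
#' restores whatever `.Random.seed` was in place before the call, so library
#' code never disturbs the caller's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a root seed plus a small offset to a new seed below 2^31 with a
#' Lehmer-style multiplicative step, so that independent pipeline stages
#' (phantom structure, pixel noise, fold shuffling, network initialization,
#' dropout) consume documented, non-overlapping streams from one root seed.
#'
#' @param seed root integer seed.
#' @param offset non-negative integer identifying the sub-stream.
#' @return A single integer in \[1, 2^31 - 2\].
#' @export
deriveSeed <- function(seed, offset = 0L) {
  s <- (abs(as.double(seed)) %% 2147483646) + 1
  for (i in seq_len(offset + 1L)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  x
}

assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

assertNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name, min, max)
  as.numeric(x)
}

clamp01 <- function(x) pmin(1, pmax(0, x))
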