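#' Null-coalescing helper
#' @param x,y values; \code{y} is used when \code{x} is NULL
#' @return \code{x} unless it is NULL, else \code{y}
#' @name null-coalesce
#' @export
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic splitting so technical repeats and pipeline stages consume
#' independent, reproducible streams. Result is always in [0, 2^31 - 2].
#'
#' @param seed master seed (single integer-like number)
#' @param k child index (non-negative integer)
#' @return a single integer seed
#' @export
childSeed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  as.integer(((abs(seed) + 1) * 1000003 + k * 7919) %% 2147483647)
}

# run expr with a locally set seed, leaving the caller's RNG state alone
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

streamFactor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    # documented numeric mapping: 0 = DexDem, 1 = DexAem, 2 = AexAem
    out <- factor(PHOTON_STREAMS[x + 1L], levels = PHOTON_STREAMS)
    if (anyNA(out) && !anyNA(x))
      stop("stream codes must be 0, 1 or 2", call. = FALSE)
    return(out)
  }
  factor(x, levels = PHOTON_STREAMS)
}

assertPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  invisible(x)
}
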