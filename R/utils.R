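#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed summaries in this package
#' use the conventional half-away-from-zero rule instead so that reported
#' percentages and averages match what a reader computes by hand.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
#' @examples
#' roundHalfUp(2.5)      # 3
#' roundHalfUp(-2.5)     # -3
#' roundHalfUp(4.35, 1)  # 4.4
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share of a count
#'
#' @param x numerator count(s).
#' @param total denominator count.
#' @param digits decimal places (default 1, the usual reporting precision).
#' @return percentage(s) on the 0-100 scale, rounded half away from zero.
#' @export
#' @examples
#' percentShare(528961, 819571)  # 64.5
percentShare <- function(x, total, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(total), total > 0)
  roundHalfUp(100 * x / total, digits)
}

## Deterministic sub-stream seeds: all generator randomness flows from one
## global integer seed; sub-streams are derived by a fixed LCG step so that
## independent stages do not share a stream. Kept below 2^31 - 1.
deriveSeed <- function(seed, offset) {
  as.integer((abs(seed) * 48271 + offset * 16807) %% 2147483629 + 1)
}

withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
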