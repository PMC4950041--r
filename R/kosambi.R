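#' Kosambi map function
#'
#' Converts a recombination fraction to a map distance under the Kosambi
#' mapping function, which allows for partial crossover interference:
#' d = 25 * ln((1 + 2r) / (1 - 2r)) centimorgans.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return map distance(s) in centimorgans.
#' @seealso [inverseKosambi()]
#' @export
#' @examples
#' kosambi(0.25)  # 25 * log(3) = 27.465 cM
#' kosambi(0.1)   # 10.137 cM
kosambi <- function(r) {
  if (!is.numeric(r) || any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' Converts a map distance in centimorgans to the recombination fraction of
#' the Kosambi function: r = tanh(2d / 100) / 2, with d/100 in Morgans.
#'
#' @param d map distance(s) in centimorgans, `d >= 0`.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @seealso [kosambi()]
#' @export
#' @examples
#' inverseKosambi(27.4653)  # 0.25
#' inverseKosambi(0)        # 0
inverseKosambi <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0)) {
    stop("map distance must be non-negative")
  }
  0.5 * tanh(2 * d / 100)
}
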