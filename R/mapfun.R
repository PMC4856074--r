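#' Kosambi and Haldane map functions
#'
#' Convert between recombination fractions and genetic map distance. The
#' Kosambi function, \eqn{d = 25\,\ln\{(1+2r)/(1-2r)\}} cM, allows for
#' partial crossover interference and is the convention used throughout this
#' package; the Haldane function (no interference) is provided for the
#' simulator. Both inverses are exact closed forms.
#'
#' @param rf recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in centimorgans, `d >= 0`.
#' @return Distances in cM, or recombination fractions.
#' @examples
#' kosambi_cM(0.10)       # 10.137 cM
#' kosambi_rf(kosambi_cM(0.25))
#' @export
kosambi_cM <- function(rf) {
  if (any(rf < 0 | rf >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

#' @rdname kosambi_cM
#' @export
kosambi_rf <- function(d) {
  if (any(d < 0)) stop("map distance must be nonnegative")
  0.5 * tanh(2 * d / 100)
}

#' @rdname kosambi_cM
#' @export
haldane_cM <- function(rf) {
  if (any(rf < 0 | rf >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * rf)
}

#' @rdname kosambi_cM
#' @export
haldane_rf <- function(d) {
  if (any(d < 0)) stop("map distance must be nonnegative")
  0.5 * (1 - exp(-d / 50))
}
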