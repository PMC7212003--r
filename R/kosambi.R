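#' Kosambi map function
#'
#' Convert a meiotic recombination fraction to Kosambi map distance,
#' d = 25 * ln((1 + 2r) / (1 - 2r)) centimorgans, and back. The Kosambi
#' function allows a moderate level of crossover interference and is the
#' standard choice for maize linkage maps.
#'
#' @param r meiotic recombination fraction, in `[0, 0.5)`.
#' @return Map distance in cM.
#' @seealso [kosambi_r()] for the inverse, [ril_R()] for the selfed-RIL
#'   line-level recombination expectation.
#' @export
#' @examples
#' kosambi_cm(0.25)          # 25 * log(3) = 27.465 cM
#' kosambi_r(kosambi_cm(0.1))
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @param cm map distance in cM (>= 0).
#' @export
kosambi_r <- function(cm) {
  if (any(cm < 0)) stop("map distance must be non-negative")
  e <- exp(cm / 25)
  0.5 * (e - 1) / (e + 1)
}

#' Selfed-RIL recombination expectation (Haldane-Waterman)
#'
#' For recombinant inbred lines derived by repeated selfing, the expected
#' fraction of lines recombinant between two loci with meiotic recombination
#' fraction `r` is `R = 2r / (1 + 2r)`. `ril_r()` inverts the relation,
#' `r = R / (2 - 2R)`.
#'
#' @param r meiotic recombination fraction in `[0, 0.5]`.
#' @return Line-level recombinant fraction `R` in `[0, 0.5]`.
#' @export
ril_R <- function(r) 2 * r / (1 + 2 * r)

#' @rdname ril_R
#' @param R line-level recombinant fraction in `[0, 0.5)`.
#' @export
ril_r <- function(R) R / (2 - 2 * R)
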