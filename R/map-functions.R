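#' Map functions: genetic distance to recombination fraction
#'
#' `haldane_c()` converts a map distance in cM to a recombination fraction
#' under the Haldane (no-interference) map function,
#' c = (1 - exp(-2d/100)) / 2. `kosambi_c()` implements the Kosambi function,
#' c = tanh(2d/100) / 2, offered for interpreting externally supplied maps;
#' all internal meiosis and transmission machinery uses Haldane, under which
#' crossovers form a Markov process along the chromosome.
#'
#' @param d_cm Map distance(s) in centimorgans (non-negative).
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
#' @examples
#' haldane_c(10)   # ~0.0906
#' haldane_c(0)    # 0
haldane_c <- function(d_cm) {
  if (any(d_cm < 0)) stop("distances must be non-negative", call. = FALSE)
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' @rdname haldane_c
#' @export
kosambi_c <- function(d_cm) {
  if (any(d_cm < 0)) stop("distances must be non-negative", call. = FALSE)
  tanh(2 * d_cm / 100) / 2
}
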