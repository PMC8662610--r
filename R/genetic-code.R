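#' The standard genetic code over the 61 sense codons
#'
#' Returns the standard genetic code as used throughout the package: the
#' mapping from all 64 codons to amino acids (stop codons as `"*"`), the
#' ordered vector of 61 sense codons that defines the codon state space of all
#' substitution models, and the index of each sense codon in that space.
#'
#' @return A list with components `codon_to_aa` (named character vector of
#'   length 64), `sense_codons` (character vector of length 61),
#'   `stop_codons` (length 3) and `codon_index` (named integer vector mapping
#'   each sense codon to its 1-based state index).
#' @export
#' @examples
#' code <- genetic_code()
#' length(code$sense_codons) # 61
genetic_code <- function() {
  if (!is.null(.sc_env$code)) {
    return(.sc_env$code)
  }
  nts <- c("T", "C", "A", "G")
  codons <- as.vector(outer(
    outer(nts, nts, function(a, b) paste0(a, b)),
    nts, paste0
  ))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1))
  sense <- codons[aa != "*"]
  stopifnot(length(sense) == 61L)
  code <- list(
    codon_to_aa = aa,
    sense_codons = sense,
    stop_codons = codons[aa == "*"],
    codon_index = setNames(seq_along(sense), sense)
  )
  .sc_env$code <- code
  code
}

#' Translate codons to amino acids
#'
#' @param codons Character vector of codons (3 letters each); `"---"` and
#'   codons containing gaps or ambiguity codes translate to `NA`.
#' @return Character vector of one-letter amino-acid symbols (`"*"` for stop).
#' @export
translate_codons <- function(codons) {
  code <- genetic_code()
  out <- unname(code$codon_to_aa[codons])
  out
}

# is this a clean codon over ACGT? (anything else -> treated as missing)
.is_plain_codon <- function(codons) {
  grepl("^[ACGT]{3}$", codons)
}
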