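#' Construct a codon alignment
#'
#' A codon alignment is stored as a character matrix with one row per taxon and
#' one column per codon site. Codons containing gaps or IUPAC ambiguity codes
#' are kept verbatim but are treated as fully missing states by all likelihood
#' computations (the likelihood then sums over all 61 sense codons).
#'
#' @param seqs Named character vector of aligned nucleotide sequences (equal
#'   lengths, divisible by 3), or a codon character matrix with rownames.
#' @return An object of class `codon_alignment` (a character matrix of codons).
#' @export
#' @examples
#' aln <- codon_alignment(c(a = "ATGAAA", b = "ATG---"))
#' dim(aln) # 2 taxa x 2 codon sites
codon_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stop("sequences must be named")
    n <- unique(nchar(seqs))
    if (length(n) != 1L) stop("rows have unequal length")
    if (n %% 3L != 0L) stop("alignment length not divisible by 3")
    m <- t(vapply(seqs, function(s) {
      substring(toupper(s), seq(1L, n, 3L), seq(3L, n, 3L))
    }, character(n / 3L)))
    if (n / 3L == 1L) m <- matrix(m, ncol = 1L, dimnames = list(names(seqs), NULL))
  }
  structure(m, class = c("codon_alignment", class(m)))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", nrow(x), "taxa x", ncol(x), "codon sites (",
      3L * ncol(x), "nt )\n")
  invisible(x)
}

#' Taxa of a codon alignment
#' @param aln A `codon_alignment`.
#' @return Character vector of taxon names.
#' @export
alignment_taxa <- function(aln) rownames(aln)

#' Collapse a codon alignment back to nucleotide strings
#' @param aln A `codon_alignment`.
#' @return Named character vector of sequences.
#' @export
alignment_sequences <- function(aln) {
  setNames(apply(unclass(aln), 1L, paste0, collapse = ""), rownames(aln))
}

# integer state matrix: 1..61 sense-codon index, 0 = missing (gap/ambiguous)
as_state_matrix <- function(aln) {
  code <- genetic_code()
  m <- unclass(aln)
  idx <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  plain <- .is_plain_codon(m)
  hit <- plain & m %in% code$sense_codons
  idx[hit] <- code$codon_index[m[hit]]
  idx
}

#' Validate a codon alignment against the pipeline's filtering rules
#'
#' An analysis-ready alignment must contain no stop codons, be at least 80
#' nucleotides long after trimming, and retain at least four taxa. Instead of
#' raising an error, rule failures are returned as a rejection record so that
#' the pipeline can log why an orthogroup was excluded.
#'
#' @param aln A `codon_alignment`.
#' @param min_length_nt Minimum alignment length in nucleotides (default 80).
#' @param min_taxa Minimum number of taxa (default 4).
#' @return A list with `ok = TRUE` and the alignment, or `ok = FALSE` and the
#'   failed `rule` (`"internal_stop"`, `"min_length_80nt"` or
#'   `"min_4_species"`).
#' @export
validate_codon_alignment <- function(aln, min_length_nt = 80L, min_taxa = 4L) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- genetic_code()
  m <- unclass(aln)
  plain <- .is_plain_codon(m)
  if (any(m[plain] %in% code$stop_codons)) {
    return(list(ok = FALSE, rule = "internal_stop"))
  }
  if (3L * ncol(m) < min_length_nt) {
    return(list(ok = FALSE, rule = "min_length_80nt"))
  }
  if (nrow(m) < min_taxa) {
    return(list(ok = FALSE, rule = "min_4_species"))
  }
  list(ok = TRUE, alignment = aln)
}
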