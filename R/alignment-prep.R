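#' Back-translate an amino-acid alignment to a codon alignment
#'
#' Each amino-acid column becomes one codon column; alignment gaps become
#' `"---"`. Every coding sequence must translate exactly to its ungapped
#' amino-acid row (a terminal stop codon on the CDS is tolerated and
#' stripped).
#'
#' @param aa_aln Named character vector: the aligned amino-acid sequences
#'   (equal lengths, `-` for gaps).
#' @param cds Named character vector: unaligned coding sequences covering
#'   every id in `aa_aln`.
#' @return A [codon_alignment()].
#' @export
backtranslate <- function(aa_aln, cds) {
  stopifnot(!is.null(names(aa_aln)))
  miss <- setdiff(names(aa_aln), names(cds))
  if (length(miss)) stop("no CDS for: ", paste(miss, collapse = ", "))
  code <- genetic_code()
  rows <- lapply(names(aa_aln), function(id) {
    aa <- strsplit(toupper(aa_aln[[id]]), "")[[1]]
    nt <- gsub("U", "T", toupper(cds[[id]]), fixed = TRUE)
    if (nchar(nt) %% 3L != 0L) {
      stop("CDS length of '", id, "' is not a multiple of 3")
    }
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
    # tolerate and strip one terminal stop codon
    if (length(codons) && codons[length(codons)] %in% code$stop_codons) {
      codons <- codons[-length(codons)]
    }
    naa <- sum(aa != "-")
    if (length(codons) != naa) {
      stop("CDS of '", id, "' has ", length(codons),
           " codons but the ungapped amino-acid row has ", naa)
    }
    tr <- translate_codons(codons)
    tr[!.is_plain_codon(codons)] <- NA
    mismatch <- which(!is.na(tr) & tr != aa[aa != "-"] & aa[aa != "-"] != "X")
    if (length(mismatch)) {
      stop("translation mismatch for '", id, "' at amino-acid position ",
           mismatch[1L])
    }
    out <- rep("---", length(aa))
    out[aa != "-"] <- codons
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(aa_aln)
  codon_alignment(m)
}

#' Trim codon columns by amino-acid column reliability score
#'
#' Removes exactly the codon columns whose corresponding amino-acid column
#' score is less than or equal to the threshold; the order of remaining
#' columns is preserved.
#'
#' @param aln A [codon_alignment()].
#' @param scores Numeric vector, one score per codon column.
#' @param threshold Columns with `score <= threshold` are removed (default 3).
#' @return The trimmed `codon_alignment`.
#' @export
trim_columns_by_score <- function(aln, scores, threshold = 3) {
  if (length(scores) != ncol(aln)) {
    stop("got ", length(scores), " scores for ", ncol(aln), " codon columns")
  }
  keep <- scores > threshold
  codon_alignment(unclass(aln)[, keep, drop = FALSE])
}

#' Drop sequences that are mostly gaps after trimming
#'
#' A row survives if its gap-less length (number of codons containing no gap
#' character) is at least `min_fraction` of the number of alignment columns.
#'
#' @param aln A [codon_alignment()].
#' @param min_fraction Minimum retained fraction (default 0.5).
#' @return The filtered `codon_alignment` (possibly with fewer than 4 taxa;
#'   downstream validation then rejects the alignment).
#' @export
drop_short_sequences <- function(aln, min_fraction = 0.5) {
  m <- unclass(aln)
  ungapped <- rowSums(matrix(!grepl("-", m, fixed = TRUE), nrow(m)))
  keep <- ungapped / ncol(m) >= min_fraction
  codon_alignment(m[keep, , drop = FALSE])
}

#' An orthogroup ready for model fitting
#'
#' Bundles a validated codon alignment with the species tree pruned to the
#' alignment's taxa, the annotation group inherited from the reference-species
#' member, and counts of phylogenetically independent losses and reductions
#' represented among the taxa.
#'
#' @param og_id Orthogroup identifier.
#' @param alignment A validated [codon_alignment()].
#' @param tree A [labeled_tree()] whose tips equal the alignment taxa.
#' @param annotation_group Annotation group label (or `NA`).
#' @param species_lt Optional full species tree used to count transitions.
#' @return An object of class `orthogroup`.
#' @export
orthogroup <- function(og_id, alignment, tree, annotation_group = NA_character_,
                       species_lt = NULL) {
  if (!setequal(rownames(alignment), tree$tree$tip.label)) {
    stop("alignment taxa and tree tips differ")
  }
  n_loss <- n_red <- NA_integer_
  if (!is.null(species_lt)) {
    n_loss <- count_independent_transitions(rownames(alignment), species_lt, "loss")
    n_red <- count_independent_transitions(rownames(alignment), species_lt, "reduction")
  }
  structure(list(og_id = og_id, alignment = alignment, tree = tree,
                 annotation_group = annotation_group,
                 n_independent_losses = n_loss,
                 n_independent_reductions = n_red),
            class = "orthogroup")
}

#' @export
print.orthogroup <- function(x, ...) {
  cat("orthogroup", x$og_id, ":", nrow(x$alignment), "taxa,",
      ncol(x$alignment), "codons, group =", x$annotation_group, "\n")
  invisible(x)
}

#' Prepare one orthogroup from raw inputs
#'
#' Applies the fixed filtering order: back-translation, column trimming by
#' reliability score, removal of mostly-gap sequences, validation (no stop
#' codons, >= 80 nt, >= 4 taxa), then species-tree pruning.
#'
#' @param og_id Orthogroup identifier.
#' @param aa_aln Named character vector of aligned amino-acid sequences,
#'   names are taxa (or `species@transcript` labels; species are taken before
#'   `delim`).
#' @param cds Named character vector of coding sequences.
#' @param scores Per-column reliability scores.
#' @param species_lt The full species [labeled_tree()].
#' @param annotation_group Annotation group label.
#' @param score_threshold Columns with score `<=` this are removed (default 3).
#' @param min_fraction Minimum gap-less fraction per sequence (default 0.5).
#' @param delim Species delimiter in sequence names (default `"@"`).
#' @return A list: `ok = TRUE` with the [orthogroup()], or `ok = FALSE` with
#'   the rejection `rule`.
#' @export
prepare_orthogroup <- function(og_id, aa_aln, cds, scores, species_lt,
                               annotation_group = NA_character_,
                               score_threshold = 3, min_fraction = 0.5,
                               delim = "@") {
  aln <- backtranslate(aa_aln, cds)
  aln <- trim_columns_by_score(aln, scores, score_threshold)
  aln <- drop_short_sequences(aln, min_fraction)
  v <- validate_codon_alignment(aln)
  if (!v$ok) return(list(ok = FALSE, rule = v$rule, og_id = og_id))
  aln <- v$alignment
  rownames(aln) <- species_of(rownames(aln), delim)
  lt <- prune_species_tree(species_lt, rownames(aln))
  list(ok = TRUE,
       og = orthogroup(og_id, aln, lt, annotation_group, species_lt))
}
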