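#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [seqinr::read.fasta()] that returns uppercase sequences
#' with RNA `U` normalised to `T`. Identifiers must be unique.
#'
#' @param path Path to a FASTA file (nucleotide or amino acid).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "AA")
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(recs, function(x) attr(x, "name"), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(vapply(recs, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length in ", path)
  }
  tr
}

#' Write a tree in newick format
#'
#' @param tree A `phylo` or [labeled_tree()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "labeled_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read an annotation table
#'
#' Reads a TSV mapping transcript ids of the reference species to annotation
#' groups (e.g. testis-region / ovary-region / tail-region / ubiquitous), with
#' an optional nonnegative `expression` column (whole-body read counts).
#'
#' @param path Path to a TSV with columns `transcript`, `group` and optionally
#'   `expression`.
#' @return A data.frame with one row per transcript.
#' @export
read_annotation_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("transcript", "group") %in% names(tab))) {
    stop("annotation table needs columns 'transcript' and 'group'")
  }
  if (anyDuplicated(tab$transcript)) {
    stop("transcript mapped to more than one group: ",
         paste(unique(tab$transcript[duplicated(tab$transcript)]), collapse = ", "))
  }
  if ("expression" %in% names(tab) && any(tab$expression < 0, na.rm = TRUE)) {
    stop("negative expression level in annotation table")
  }
  tab
}

#' Read per-column alignment reliability scores
#'
#' @param path Path to a one- or two-column TSV; the last column holds the
#'   scores, one row per amino-acid (codon) column.
#' @return Numeric vector of scores.
#' @export
read_column_scores <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t")
  as.numeric(tab[[ncol(tab)]])
}

#' Species identifier of homolog-tree tip labels
#'
#' Homolog-tree tips carry transcript suffixes (`species@transcript`); the
#' species is the part before the delimiter.
#'
#' @param tips Character vector of tip labels.
#' @param delim Delimiter (default `"@"`).
#' @return Character vector of species identifiers.
#' @export
species_of <- function(tips, delim = "@") {
  vapply(strsplit(tips, delim, fixed = TRUE), `[[`, character(1), 1L)
}
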