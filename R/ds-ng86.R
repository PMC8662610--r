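# Nei-Gojobori (1986) counting machinery: per codon, the expected numbers of
# synonymous sites, and per codon pair, synonymous/nonsynonymous differences
# averaged over all shortest mutational pathways that avoid stop codons.

.ng86_tables <- function() {
  if (!is.null(.sc_env$ng86)) return(.sc_env$ng86)
  code <- genetic_code()
  sense <- code$sense_codons
  aa <- code$codon_to_aa
  nts <- c("A", "C", "G", "T")
  syn_sites <- vapply(sense, function(cd) {
    s <- 0
    ch <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      for (nt in setdiff(nts, ch[p])) {
        mut <- ch; mut[p] <- nt
        mcd <- paste(mut, collapse = "")
        if (aa[mcd] != "*" && aa[mcd] == aa[cd]) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  .sc_env$ng86 <- list(syn_sites = syn_sites)
  .sc_env$ng86
}

# average (syn, nonsyn) differences between two codons over all orderings of
# the differing positions, skipping pathways through stop codons
.ng86_pair_diffs <- function(c1, c2) {
  aa <- genetic_code()$codon_to_aa
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  diff <- which(ch1 != ch2)
  if (!length(diff)) return(c(0, 0))
  perms <- if (length(diff) == 1L) list(diff) else {
    if (length(diff) == 2L) list(diff, rev(diff)) else {
      p <- list()
      for (i in 1:3) for (j in setdiff(1:3, i)) {
        p[[length(p) + 1L]] <- diff[c(i, j, setdiff(1:3, c(i, j)))]
      }
      p
    }
  }
  tot <- c(0, 0); used <- 0L
  for (ord in perms) {
    cur <- ch1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- ch2[p]
      a1 <- aa[paste(cur, collapse = "")]; a2 <- aa[paste(nxt, collapse = "")]
      if (a2 == "*") { ok <- FALSE; break }
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + c(sd, nd); used <- used + 1L }
  }
  if (used == 0L) {
    # all pathways pass through stops; count every difference as nonsynonymous
    return(c(0, length(diff)))
  }
  tot / used
}

#' Mean pairwise synonymous divergence (Nei-Gojobori 1986)
#'
#' Proportion-based dS with Jukes-Cantor correction, averaged over all
#' sequence pairs. Saturated pairs (synonymous difference proportion
#' `>= 0.75`) are excluded from the mean and counted.
#'
#' @param aln A [codon_alignment()] with at least two taxa.
#' @return A list with `mean_ds`, the full `pairwise` matrix (NA where
#'   undefined), and `n_saturated`. `mean_ds` is `NA` with flag
#'   `all_saturated = TRUE` if no pair is estimable.
#' @export
pairwise_ds_ng86 <- function(aln) {
  stopifnot(nrow(aln) >= 2L)
  tabs <- .ng86_tables()
  code <- genetic_code()
  m <- unclass(aln)
  n <- nrow(m)
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  n_sat <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- .is_plain_codon(m[i, ]) & .is_plain_codon(m[j, ]) &
        m[i, ] %in% code$sense_codons & m[j, ] %in% code$sense_codons
      if (!any(ok)) next
      ci <- m[i, ok]; cj <- m[j, ok]
      S <- sum((tabs$syn_sites[ci] + tabs$syn_sites[cj]) / 2)
      sd <- 0
      for (s in which(ci != cj)) {
        sd <- sd + .ng86_pair_diffs(ci[s], cj[s])[1]
      }
      ps <- sd / S
      if (ps >= 0.75) {
        n_sat <- n_sat + 1L
      } else {
        D[i, j] <- D[j, i] <- -3 / 4 * log(1 - 4 / 3 * ps)
      }
    }
  }
  vals <- D[upper.tri(D)]
  list(mean_ds = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
       pairwise = D, n_saturated = n_sat,
       all_saturated = all(is.na(vals)))
}
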