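# Structural constants of the 61x61 Goldman-Yang style generator: which codon
# pairs are single-nucleotide neighbours, whether the change is a transition,
# and whether it is synonymous. Computed once and cached.
.q_structure <- function() {
  if (!is.null(.sc_env$qstruct)) return(.sc_env$qstruct)
  code <- genetic_code()
  sense <- code$sense_codons
  ns <- length(sense)
  spl <- do.call(rbind, strsplit(sense, ""))
  aa <- code$codon_to_aa[sense]
  i_idx <- j_idx <- integer(0)
  is_ts <- is_syn <- logical(0)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      diff <- which(spl[i, ] != spl[j, ])
      if (length(diff) != 1L) next
      i_idx <- c(i_idx, i); j_idx <- c(j_idx, j)
      is_ts <- c(is_ts, paste0(spl[i, diff], spl[j, diff]) %in% ts_pairs)
      is_syn <- c(is_syn, aa[i] == aa[j])
    }
  }
  .sc_env$qstruct <- list(i = i_idx, j = j_idx, ts = is_ts, syn = is_syn, ns = ns)
  .sc_env$qstruct
}

#' Build a scaled Goldman-Yang codon rate matrix
#'
#' Off-diagonal rates are nonzero only between codons differing at a single
#' nucleotide position: `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]`.
#' Rows sum to zero and the generator is scaled so that the expected
#' substitution rate at equilibrium equals 1, i.e. branch lengths are in
#' expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (> 0).
#' @param pi Equilibrium frequencies over the 61 sense codons (sums to 1).
#' @return A 61 x 61 generator matrix with attribute `pi`.
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega > 0, length(pi) == 61L,
            all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  st <- .q_structure()
  Q <- matrix(0, st$ns, st$ns)
  rate <- pi[st$j] * ifelse(st$ts, kappa, 1) * ifelse(st$syn, 1, omega)
  Q[cbind(st$i, st$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(genetic_code()$sense_codons, genetic_code()$sense_codons)
  attr(Q, "pi") <- pi
  Q
}

# spectral decomposition of a reversible generator: with D = diag(pi),
# B = D^1/2 Q D^-1/2 is symmetric; P(t) = U exp(L t) Uinv with U = D^-1/2 V.
.eigen_q <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sq, Uinv = t(e$vectors) * rep(sq, each = length(pi)),
       lambda = e$values)
}

#' Transition probabilities of a codon rate matrix
#'
#' Computes `P(t) = exp(Q t)` through the spectral decomposition of the
#' reversible generator.
#'
#' @param Q A generator from [build_rate_matrix()].
#' @param t Branch length (expected substitutions per codon, `>= 0`).
#' @return A 61 x 61 stochastic matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("Q must carry its equilibrium distribution (attr 'pi')")
  ed <- .eigen_q(Q, pi)
  P <- ed$U %*% (exp(ed$lambda * t) * ed$Uinv)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# Equilibrium substitution-rate coefficients of the unnormalised GY94
# generator: rate(omega) = a + b * omega, with a the synonymous and b the
# nonsynonymous equilibrium flux. Used to place all site classes of a mixture
# on one common scale (as codeml and HyPhy do): the class with dN/dS omega
# evolves at relative rate (a + b omega) / f, where f is the
# proportion-weighted mean rate over classes on background/reference
# branches, so branch lengths stay in expected substitutions per codon under
# the mixture while omega affects both composition and amount of change.
.rate_coeffs <- function(kappa, pi) {
  st <- .q_structure()
  flux <- pi[st$i] * pi[st$j] * ifelse(st$ts, kappa, 1)
  c(a = sum(flux[st$syn]), b = sum(flux[!st$syn]))
}

# common scale factor of a mixture model: mean equilibrium rate over classes
# on the background (partition "0") branches
.mixture_scale <- function(model, coeffs) {
  f <- 0
  for (cl in model$classes) {
    w <- if (!is.null(cl$prop_by_partition)) cl$prop_by_partition[["0"]] else cl$prop
    f <- f + w * (coeffs[["a"]] + coeffs[["b"]] * cl$omega[["0"]])
  }
  f
}

#' Empirical F3x4 codon frequencies of an alignment
#'
#' Position-specific nucleotide frequencies are estimated from all clean
#' codons (a pseudo-count of 0.5 per nucleotide per position avoids zeros),
#' multiplied per codon, stop codons zeroed out and the result renormalised
#' over the 61 sense codons.
#'
#' @param aln A [codon_alignment()].
#' @return Named numeric vector of length 61 summing to 1, all entries > 0.
#' @export
estimate_f3x4 <- function(aln) {
  code <- genetic_code()
  m <- unclass(aln)
  codons <- m[.is_plain_codon(m)]
  nts <- c("A", "C", "G", "T")
  freq <- matrix(0.5, 3, 4, dimnames = list(NULL, nts))
  if (length(codons)) {
    for (p in 1:3) {
      tab <- table(factor(substring(codons, p, p), levels = nts))
      freq[p, ] <- freq[p, ] + as.numeric(tab)
    }
  }
  freq <- freq / rowSums(freq)
  spl <- do.call(rbind, strsplit(code$sense_codons, ""))
  pi <- freq[1, spl[, 1]] * freq[2, spl[, 2]] * freq[3, spl[, 3]]
  pi <- pi / sum(pi)
  setNames(pi, code$sense_codons)
}
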