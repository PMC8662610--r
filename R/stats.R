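#' Likelihood-ratio test between nested model fits
#'
#' `statistic = 2 (lnL_alt - lnL_null)`, referred to a chi-square
#' distribution. Small negative statistics from numerical noise are clipped
#' to zero.
#'
#' @param lnl_null,lnl_alt Maximised log-likelihoods of the nested pair (or
#'   two `fit_result` objects).
#' @param df Degrees of freedom (>= 1).
#' @param tolerance Largest tolerated negative statistic before an error.
#' @return A list (`test_result`) with `statistic`, `df` and `p`.
#' @export
lrt <- function(lnl_null, lnl_alt, df, tolerance = 1e-4) {
  if (inherits(lnl_null, "fit_result")) lnl_null <- lnl_null$lnL
  if (inherits(lnl_alt, "fit_result")) lnl_alt <- lnl_alt$lnL
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (lnl_alt - lnl_null)
  if (stat < -max(tolerance, 2 * tolerance)) {
    warning("alternative log-likelihood below null by ", -stat / 2)
  }
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = as.integer(df),
                 p = pchisq(stat, df, lower.tail = FALSE)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("statistic =", signif(x$statistic, 5),
      if (!is.null(x$df)) paste(", df =", x$df),
      ", p =", signif(x$p, 4), "\n")
  invisible(x)
}

#' Storey q-values with pi0 estimation
#'
#' Estimates the proportion of true nulls pi0 on the lambda grid
#' 0.05, 0.10, ..., 0.95 using either the natural-spline smoother or the
#' bootstrap, then computes
#' `q_(i) = min_(j >= i) pi0 * m * p_(j) / j` over the ordered p-values.
#' q-values are monotone in p and never exceed the estimated pi0. With fewer
#' than 10 p-values, pi0 falls back to 1 (Benjamini-Hochberg equivalent) with
#' a warning.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @param method `"smoother"` (default) or `"bootstrap"`.
#' @param pi0 Optional: force a pi0 value (e.g. `pi0 = 1` for BH).
#' @return A list with `qvalues` (same order as input) and `pi0`.
#' @export
qvalues <- function(pvals, method = c("smoother", "bootstrap"), pi0 = NULL) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  m <- length(pvals)
  if (is.null(pi0)) {
    if (m < 10L) {
      warning("fewer than 10 p-values; using pi0 = 1 (BH-equivalent)")
      pi0 <- 1
    } else {
      lam <- seq(0.05, 0.95, 0.05)
      pi0_lam <- vapply(lam, function(l) mean(pvals > l) / (1 - l), numeric(1))
      if (method == "smoother") {
        fit <- smooth.spline(lam, pi0_lam, df = 3)
        pi0 <- predict(fit, x = max(lam))$y
      } else {
        # bootstrap: pick the lambda minimising estimated MSE around the
        # minimum of the pi0(lambda) curve
        minp <- min(pi0_lam)
        mse <- vapply(seq_along(lam), function(i) {
          boots <- vapply(1:100, function(b) {
            pb <- sample(pvals, m, replace = TRUE)
            mean(pb > lam[i]) / (1 - lam[i])
          }, numeric(1))
          mean((boots - minp)^2)
        }, numeric(1))
        pi0 <- pi0_lam[which.min(mse)]
      }
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  ord <- order(pvals)
  q <- pi0 * m * pvals[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, pi0)
  out <- numeric(m)
  out[ord] <- q
  list(qvalues = out, pi0 = pi0)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic referred to chi-square with k - 1 df (wraps
#' [stats::kruskal.test()]; identical values H = 0, p = 1 are handled
#' explicitly).
#'
#' @param groups List of numeric vectors.
#' @return A `test_result` with `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, sum(lengths(groups)) >= 2L)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    return(structure(list(statistic = 0, df = length(groups) - 1L, p = 1),
                     class = "test_result"))
  }
  kt <- kruskal.test(x, g)
  structure(list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value),
            class = "test_result")
}

#' Dwass-Steele-Critchlow-Fligner all-pairs post-hoc test
#'
#' For each pair of groups a two-sample rank statistic (tie-corrected) is
#' standardised and referred to the studentized-range distribution with k
#' groups and infinite degrees of freedom (large-sample reference).
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each with >= 2
#'   observations).
#' @return Symmetric matrix of pairwise p-values (diagonal NA).
#' @export
dscf_posthoc <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 3L)
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  P <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- groups[[i]]; xj <- groups[[j]]
      ni <- length(xi); nj <- length(xj); N <- ni + nj
      r <- rank(c(xi, xj))
      Rj <- sum(r[(ni + 1L):N])
      ties <- table(c(xi, xj))
      sigma2 <- ni * nj / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      z <- (Rj - nj * (N + 1) / 2) / sqrt(sigma2)
      P[i, j] <- P[j, i] <- ptukey(sqrt(2) * abs(z), k, Inf, lower.tail = FALSE)
    }
  }
  P
}

#' Chi-square goodness of fit against expected annotation-group proportions
#'
#' Tests whether significant orthogroups are distributed across annotation
#' groups as expected from the distribution of all tested orthogroups:
#' `E_g = (sum O) T_g / (sum T)`, df = number of groups - 1.
#'
#' @param observed Named vector of observed significant counts per group.
#' @param totals Vector of total tested counts per group (same order).
#' @return A `test_result` with `statistic`, `df`, `p` and the `expected`
#'   counts.
#' @export
chi_square_expected <- function(observed, totals) {
  stopifnot(length(observed) == length(totals), all(totals > 0),
            all(observed >= 0), all(observed <= totals))
  if (sum(observed) == 0) stop("no significant observations")
  ct <- suppressWarnings(chisq.test(observed, p = totals / sum(totals)))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, expected = unname(ct$expected)),
            class = "test_result")
}

#' Classify the pattern of dN/dS across the three bristle states
#'
#' Coarse pattern: sign of `w_absent - w_present` (`"-"` decreasing, `"+"`
#' increasing). Fine pattern: signs of the reduced-vs-present and
#' absent-vs-reduced steps, e.g. `"-/+"`. Exact ties classify as `"+"` and
#' set the tie flag.
#'
#' @param w_present,w_reduced,w_absent Positive dN/dS estimates per state.
#' @return A list with `coarse`, `fine` and `tie`.
#' @export
classify_omega_pattern <- function(w_present, w_reduced, w_absent) {
  stopifnot(w_present > 0, w_reduced > 0, w_absent > 0)
  sgn <- function(d) if (d >= 0) "+" else "-"
  tie <- (w_absent == w_present) || (w_reduced == w_present) ||
    (w_absent == w_reduced)
  list(coarse = sgn(w_absent - w_present),
       fine = paste0(sgn(w_reduced - w_present), "/", sgn(w_absent - w_reduced)),
       tie = tie)
}

#' Karlin-Mrazek codon-usage bias of a gene against a reference set
#'
#' `B = sum_a f_a(gene) sum_(c in codons(a)) | p(c|a, gene) - p(c|a, ref) |`,
#' where `f_a` is the amino-acid frequency in the gene and `p(c|a, .)` are
#' within-family codon frequencies. Single-codon families contribute 0.
#'
#' @param gene_codons Named vector of codon counts for the gene.
#' @param reference_codons Named vector of codon counts for the reference set;
#'   must cover every amino-acid family present in the gene.
#' @return The bias B (a number in `[0, 2]`).
#' @export
codon_usage_bias_b <- function(gene_codons, reference_codons) {
  code <- genetic_code()
  gene_codons <- gene_codons[names(gene_codons) %in% code$sense_codons]
  reference_codons <- reference_codons[names(reference_codons) %in% code$sense_codons]
  if (!length(gene_codons) || sum(gene_codons) == 0) stop("empty gene")
  aa_of <- code$codon_to_aa[code$sense_codons]
  fam <- split(code$sense_codons, aa_of)
  gtot <- sum(gene_codons)
  B <- 0
  for (a in names(fam)) {
    cds <- fam[[a]]
    g <- sum(gene_codons[cds], na.rm = TRUE)
    if (g == 0 || length(cds) == 1L) next
    r <- sum(reference_codons[cds], na.rm = TRUE)
    if (r == 0) stop("reference has no codons for amino acid ", a)
    pg <- ifelse(is.na(gene_codons[cds]), 0, gene_codons[cds]) / g
    pr <- ifelse(is.na(reference_codons[cds]), 0, reference_codons[cds]) / r
    B <- B + (g / gtot) * sum(abs(pg - pr))
  }
  unname(B)
}

#' Spearman rank correlation test
#'
#' Rank correlation with tie handling; exact permutation p-value for
#' `n <= 9` without ties, t-approximation otherwise (wraps
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A `test_result` with `statistic` (rho) and `p`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(rank(x))) == 1L || length(unique(rank(y))) == 1L) {
    stop("zero variance in ranks")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = length(x) <= 9L)
  )
  structure(list(statistic = unname(ct$estimate), df = NULL, p = ct$p.value),
            class = "test_result")
}
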