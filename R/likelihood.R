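# --- mixture model specifications -------------------------------------------
# A model spec is a list(kappa, pi, classes) where classes is a list of
# list(prop, omega) and omega is a named vector mapping branch-partition
# labels ("0", "1", "2") to dN/dS values for that site class.

#' Single-omega (M0) model specification
#' @param kappa Transition/transversion ratio.
#' @param omega dN/dS applied to every branch.
#' @param pi Equilibrium codon frequencies (61-vector).
#' @return A model specification for [log_likelihood()].
#' @export
model_m0 <- function(kappa, omega, pi) {
  list(kappa = kappa, pi = pi,
       classes = list(list(prop = 1,
                           omega = c("0" = omega, "1" = omega, "2" = omega))))
}

#' Branch-model specification with one omega per branch partition
#' @param kappa Transition/transversion ratio.
#' @param omegas Named vector of dN/dS per partition label (e.g.
#'   `c("0" = .1, "1" = .3, "2" = .9)`).
#' @param pi Equilibrium codon frequencies.
#' @return A model specification.
#' @export
model_branch <- function(kappa, omegas, pi) {
  list(kappa = kappa, pi = pi,
       classes = list(list(prop = 1, omega = omegas)))
}

#' Branch-site model A specification
#'
#' Four site classes 0, 1, 2a, 2b with proportions `p0`, `p1`,
#' `p2a = (1-p0-p1) p0/(p0+p1)`, `p2b = (1-p0-p1) p1/(p0+p1)`. Background
#' branches see omega (w0, 1, w0, 1) across the classes, foreground branches
#' (partition `"1"`) see (w0, 1, w2, w2); the null model fixes `w2 = 1`.
#'
#' @param kappa Transition/transversion ratio.
#' @param w0 Purifying-class dN/dS, in (0, 1).
#' @param w2 Positive-selection-class dN/dS on the foreground (`>= 1`).
#' @param p0,p1 Proportions of site classes 0 and 1 (`p0 + p1 <= 1`).
#' @param pi Equilibrium codon frequencies.
#' @return A model specification.
#' @export
model_a <- function(kappa, w0, w2, p0, p1, pi) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12)
  pr <- p0 + p1
  p2a <- if (pr > 0) (1 - pr) * p0 / pr else (1 - pr) / 2
  p2b <- if (pr > 0) (1 - pr) * p1 / pr else (1 - pr) / 2
  list(kappa = kappa, pi = pi,
       classes = list(
         list(prop = p0,  omega = c("0" = w0, "1" = w0)),
         list(prop = p1,  omega = c("0" = 1,  "1" = 1)),
         list(prop = p2a, omega = c("0" = w0, "1" = w2)),
         list(prop = p2b, omega = c("0" = 1,  "1" = w2))))
}

#' Selection-intensity (RELAX-style) model specification
#'
#' Three dN/dS categories with reference values
#' `w[1] <= w[2] <= 1 <= w[3]`; on test branches (partition `"1"`) each
#' category value is raised to the selection-intensity exponent `k`
#' (`omega^k`), so `k < 1` relaxes and `k > 1` intensifies selection; `k = 1`
#' is the null. Following the branch-site random-effects framework the method
#' is defined in, the category is drawn independently for every branch and
#' site, so each branch's transition kernel is the proportion-weighted
#' mixture of its partition's category matrices.
#'
#' @param kappa Transition/transversion ratio.
#' @param w Length-3 vector of reference category dN/dS values.
#' @param p Length-3 vector of category proportions (sums to 1).
#' @param k Selection-intensity exponent (> 0).
#' @param pi Equilibrium codon frequencies.
#' @return A model specification.
#' @export
model_relax <- function(kappa, w, p, k, pi) {
  stopifnot(length(w) == 3L, length(p) == 3L, abs(sum(p) - 1) < 1e-8, k > 0)
  classes <- lapply(1:3, function(i) {
    list(prop = p[i], omega = c("0" = unname(w[i]), "1" = unname(w[i]^k)))
  })
  list(kappa = kappa, pi = pi, classes = classes, sharing = "branch")
}

#' Partitioned descriptive model (PDM) specification
#'
#' Independent three-category dN/dS distributions (values and proportions) for
#' reference and test branches, in the same branch-site random-effects form
#' as [model_relax()] (which it therefore nests). Descriptive only; no
#' hypothesis test is attached.
#'
#' @param kappa Transition/transversion ratio.
#' @param w_ref,p_ref Reference-branch category values and proportions.
#' @param w_test,p_test Test-branch category values and proportions.
#' @param pi Equilibrium codon frequencies.
#' @return A model specification.
#' @export
model_pdm <- function(kappa, w_ref, p_ref, w_test, p_test, pi) {
  stopifnot(length(w_ref) == 3L, length(w_test) == 3L,
            abs(sum(p_ref) - 1) < 1e-8, abs(sum(p_test) - 1) < 1e-8)
  classes <- lapply(1:3, function(i) {
    list(prop_by_partition = list("0" = p_ref[i], "1" = p_test[i]),
         omega = c("0" = unname(w_ref[i]), "1" = unname(w_test[i])))
  })
  list(kappa = kappa, pi = pi, classes = classes, sharing = "branch")
}

# --- pattern compression -----------------------------------------------------

# compress alignment columns into unique site patterns
.site_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  list(states = states[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]),
       map = match(key, key[u]))
}

# --- likelihood --------------------------------------------------------------

# spectral decomposition with an optional per-fit cache; during quasi-Newton
# fitting most gradient perturbations leave (kappa, omega) pairs unchanged,
# so caching decompositions across objective evaluations saves most of the
# eigen work (pi is constant within a fit, so the key omits it)
.eigen_cached <- function(kappa, omega, pi, cache = NULL) {
  if (is.null(cache)) {
    return(.eigen_q(build_rate_matrix(kappa, omega, pi), pi))
  }
  key <- paste0("k", signif(kappa, 15), "w", signif(omega, 15))
  ed <- cache[[key]]
  if (is.null(ed)) {
    ed <- .eigen_q(build_rate_matrix(kappa, omega, pi), pi)
    if (length(ls(cache)) > 400L) rm(list = ls(cache), envir = cache)
    cache[[key]] <- ed
  }
  ed
}

# per-pattern per-class log-likelihood matrix (npat x nclass)
.class_site_loglik <- function(states_pat, tree, branch_labels, model,
                               scale = 1, cache = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  lab_by_child <- integer(ntip + tr$Nnode)
  lab_by_child[tree$edge[, 2]] <- branch_labels
  elab <- lab_by_child[tr$edge[, 2]]
  tlen <- tr$edge.length * scale

  tips <- states_pat[tr$tip.label, , drop = FALSE]
  storage.mode(tips) <- "integer"

  # unique omegas across classes -> one spectral decomposition each
  all_om <- unlist(lapply(model$classes, function(cl) cl$omega[as.character(elab)]))
  uom <- unique(signif(all_om, 12))
  ns <- 61L
  U <- array(0, c(ns, ns, length(uom)))
  Uinv <- array(0, c(ns, ns, length(uom)))
  lam <- matrix(0, ns, length(uom))
  for (m in seq_along(uom)) {
    ed <- .eigen_cached(model$kappa, uom[m], model$pi, cache)
    U[, , m] <- ed$U; Uinv[, , m] <- ed$Uinv; lam[, m] <- ed$lambda
  }
  npat <- ncol(tips)
  co <- .rate_coeffs(model$kappa, model$pi)
  f <- .mixture_scale(model, co)
  out <- matrix(0, npat, length(model$classes))
  for (ci in seq_along(model$classes)) {
    om_raw <- model$classes[[ci]]$omega[as.character(elab)]
    om_e <- signif(om_raw, 12)
    mat_id <- match(om_e, uom)
    # common mixture scaling: this class's relative rate per edge
    tlen_c <- tlen * (co[["a"]] + co[["b"]] * om_raw) / f
    out[, ci] <- pruning_loglik_cpp(tr$edge, tlen_c, as.integer(mat_id),
                                    U, Uinv, lam, tips, model$pi,
                                    ntip + tr$Nnode)
  }
  out
}

# branch-site random-effects likelihood: every branch's transition kernel is
# the proportion-weighted mixture of its partition's per-category matrices
# (the omega category is drawn independently per branch and site)
.branch_mix_loglik <- function(states_pat, tree, branch_labels, model,
                               scale = 1, cache = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  lab_by_child <- integer(ntip + tr$Nnode)
  lab_by_child[tree$edge[, 2]] <- branch_labels
  elab <- as.character(lab_by_child[tr$edge[, 2]])
  tlen <- tr$edge.length * scale
  tips <- states_pat[tr$tip.label, , drop = FALSE]
  storage.mode(tips) <- "integer"

  all_om <- unlist(lapply(model$classes, function(cl) cl$omega[elab]))
  uom <- unique(signif(all_om, 12))
  ns <- 61L
  U <- array(0, c(ns, ns, length(uom)))
  Uinv <- array(0, c(ns, ns, length(uom)))
  lam <- matrix(0, ns, length(uom))
  for (m in seq_along(uom)) {
    ed <- .eigen_cached(model$kappa, uom[m], model$pi, cache)
    U[, , m] <- ed$U; Uinv[, , m] <- ed$Uinv; lam[, m] <- ed$lambda
  }
  nedge <- nrow(tr$edge)
  ncomp <- length(model$classes)
  co <- .rate_coeffs(model$kappa, model$pi)
  f <- .mixture_scale(model, co)
  mat_ids <- matrix(1L, nedge, ncomp)
  wts <- matrix(0, nedge, ncomp)
  tmat <- matrix(0, nedge, ncomp)
  for (ci in seq_len(ncomp)) {
    cl <- model$classes[[ci]]
    om_raw <- cl$omega[elab]
    mat_ids[, ci] <- match(signif(om_raw, 12), uom)
    wts[, ci] <- if (!is.null(cl$prop_by_partition)) {
      unlist(cl$prop_by_partition[elab], use.names = FALSE)
    } else cl$prop
    tmat[, ci] <- tlen * (co[["a"]] + co[["b"]] * om_raw) / f
  }
  pruning_loglik_mix_cpp(tr$edge, tmat, mat_ids, wts, U, Uinv, lam, tips,
                         model$pi, ntip + tr$Nnode)
}

# full machinery: returns loglik plus pieces needed for posteriors
.log_likelihood_full <- function(aln, lt, model, scale = 1) {
  states <- as_state_matrix(aln)
  pat <- .site_patterns(states)
  if (identical(model$sharing, "branch")) {
    site_ll <- .branch_mix_loglik(pat$states, lt$tree, lt$branch_labels,
                                  model, scale)
    return(list(loglik = sum(pat$weights * site_ll), site_loglik = site_ll,
                class_loglik = NULL, props = NULL, pattern_map = pat$map,
                weights = pat$weights))
  }
  cl <- .class_site_loglik(pat$states, lt$tree, lt$branch_labels, model, scale)
  props <- vapply(model$classes, `[[`, numeric(1), "prop")
  keep <- props > 0
  lw <- sweep(cl[, keep, drop = FALSE], 2L, log(props[keep]), `+`)
  mx <- apply(lw, 1L, max)
  site_ll <- mx + log(rowSums(exp(lw - mx)))
  list(loglik = sum(pat$weights * site_ll), site_loglik = site_ll,
       class_loglik = cl, props = props, pattern_map = pat$map,
       weights = pat$weights)
}

#' Log-likelihood of a codon alignment under a mixture codon model
#'
#' Felsenstein pruning over compressed site patterns, with per-branch
#' partition-specific dN/dS within each site class and the mixture taken over
#' site classes:
#' `lnL = sum_patterns m_p log sum_c prop_c L_p(c)`.
#'
#' @param aln A [codon_alignment()] whose taxa equal the tree's tips.
#' @param tree A [labeled_tree()] (its `branch_labels` select each branch's
#'   partition within each site class).
#' @param model A model specification from [model_m0()], [model_branch()],
#'   [model_a()], [model_relax()] or [model_pdm()].
#' @param scale Multiplier applied to the tree's branch lengths to convert
#'   them to expected substitutions per codon (default 1).
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(aln, tree, model, scale = 1) {
  if (!setequal(rownames(aln), tree$tree$tip.label)) {
    stop("alignment taxa and tree tips differ")
  }
  .log_likelihood_full(aln, tree, model, scale)$loglik
}
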