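# One shared orthogroup per regime keeps this file fast; fits on 6-8 taxa and
# 100-150 codons take well under a second each.

lt_fit <- fixture_labeled_tree(6, absent = c("sp2", "sp5"), reduced = "sp3",
                               height = 0.5, seed = 21)

test_that("the single-omega fit improves on its starting point and respects
           reporting caps", {
  og <- fixture_orthogroup(lt_fit, "m0", list(kappa = 2, omega = 0.25),
                           n_codons = 150, seed = 22)
  fit <- fit_single_omega(og)
  init <- model_m0(2, 0.001, fit$fixed$pi)
  lnl_init <- log_likelihood(og$alignment, og$tree, init, scale = 1)
  expect_gte(fit$lnL, lnl_init)
  expect_true(fit$converged)
  expect_equal(fit$params$omega_reported,
               cap_omega(fit$params$omega))

  # caps apply only to reported values
  expect_equal(cap_omega(c(0.0001, 0.5, 33)), c(0.01, 0.5, 10))
})

test_that("an alignment with only synonymous differences drives omega to the
           reporting floor", {
  # two leucine codons differing synonymously, repeated
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
  lt <- labeled_tree(tr)
  block_a <- paste(rep(c("CTT", "AAA", "GGG", "TTT", "CCC"), 8), collapse = "")
  block_b <- paste(rep(c("CTC", "AAA", "GGG", "TTT", "CCC"), 8), collapse = "")
  aln <- codon_alignment(c(a = block_a, b = block_b, c = block_a, d = block_b))
  og <- orthogroup("syn", aln, lt)
  fit <- fit_single_omega(og)
  expect_lt(fit$params$omega, 0.01)
  expect_equal(fit$params$omega_reported, 0.01)
})

test_that("collapsing all branch labels reproduces the single-omega fit", {
  og <- fixture_orthogroup(lt_fit, "m0", list(kappa = 2, omega = 0.2),
                           n_codons = 120, seed = 23)
  m0 <- fit_single_omega(og)
  # same orthogroup with every tip relabelled background
  lt_flat <- labeled_tree(lt_fit$tree)
  og_flat <- orthogroup("flat", og$alignment, lt_flat)
  b1 <- fit_branch_three_omega(og_flat, m0 = m0, require_all_states = FALSE)
  expect_equal(b1$lnL, m0$lnL, tolerance = 1e-6)

  # a missing partition is a skip, not an error
  lt_two <- labeled_tree(lt_fit$tree,
                         setNames(c("present", "absent")[1 + (seq_len(6) %% 2)],
                                  lt_fit$tree$tip.label))
  og_two <- orthogroup("two", og$alignment, lt_two)
  skip_rec <- fit_branch_three_omega(og_two, m0 = m0)
  expect_false(isTRUE(skip_rec$ok))
  expect_equal(skip_rec$reason, "missing_partition")
})

test_that("branch-site model A nests its null and counts free parameters", {
  og <- fixture_orthogroup(
    label_contrast(lt_fit, "absent"), "modelA",
    list(kappa = 2, w0 = 0.1, w2 = 3, p0 = 0.55, p1 = 0.3),
    n_codons = 150, seed = 24)
  og <- orthogroup("ma", og$alignment, lt_fit)
  m0 <- fit_single_omega(og)
  a0 <- fit_model_a_null(og, "absent", m0 = m0)
  a1 <- fit_model_a(og, "absent", m0 = m0, init = a0)
  expect_equal(a0$params$w2, 1)
  expect_equal(a0$np, 4L)  # kappa, w0, p0, p1
  expect_equal(a1$np, 5L)
  expect_gte(a1$lnL, a0$lnL - 1e-6)

  # the alternative evaluated at w2 = 1 equals the null's likelihood surface
  mod_null <- model_a(a0$params$kappa, a0$params$w0, 1, a0$params$p0,
                      a0$params$p1, a0$fixed$pi)
  l_eval <- log_likelihood(og$alignment, label_contrast(og$tree, "absent"),
                           mod_null, scale = a0$fixed$scale)
  expect_equal(l_eval, a0$lnL, tolerance = 1e-6)
})

test_that("site posteriors normalise, never flag invariant sites, and mark
           simulated positively selected classes", {
  lt <- fixture_labeled_tree(8, absent = c("sp2", "sp5", "sp7"), reduced = NULL,
                             height = 0.6, seed = 25)
  aln <- simulate_codon_alignment(
    label_contrast(lt, "absent"), "modelA",
    list(kappa = 2, w0 = 0.05, w2 = 6, p0 = 0.6, p1 = 0.25),
    300, seed = 26)
  og <- orthogroup("post", aln, lt)
  m0 <- fit_single_omega(og)
  a1 <- fit_model_a(og, "absent", m0 = m0)
  sp <- site_posteriors(og, a1)
  expect_equal(rowSums(sp$posterior), rep(1, ncol(aln)), tolerance = 1e-10)

  # invariant sites are never flagged
  invariant <- which(apply(unclass(aln), 2, function(col) length(unique(col)) == 1L))
  expect_length(intersect(sp$flagged, invariant), 0L)

  # flagged sites enrich for the true positively selected classes (2a/2b)
  truth <- attr(aln, "site_classes") %in% c(3L, 4L)
  if (length(sp$flagged) > 0) {
    enrich <- mean(truth[sp$flagged]) / mean(truth)
    expect_gt(enrich, 1)
  }
})

test_that("the selection-intensity fit nests null, alternative and PDM and
           leaves omega = 1 categories invariant under k", {
  lt <- fixture_labeled_tree(8, absent = c("sp2", "sp5", "sp7"), reduced = NULL,
                             height = 0.5, seed = 27)
  aln <- simulate_codon_alignment(
    label_contrast(lt, "absent"), "relax",
    list(kappa = 2, w = c(0.05, 0.5, 1.5), p = c(0.5, 0.4, 0.1), k = 0.3),
    150, seed = 28)
  og <- orthogroup("rx", aln, lt)
  m0 <- fit_single_omega(og)
  r0 <- fit_relax(og, "absent", fix_k = 1, m0 = m0)
  r1 <- fit_relax(og, "absent", m0 = m0, init = r0)
  pdm <- fit_relax_pdm(og, "absent", m0 = m0, init = r1)
  expect_gte(r1$lnL, r0$lnL - 1e-4)
  expect_gte(pdm$lnL, r1$lnL - 1e-4)

  # reference category ordering constraint holds
  expect_true(all(diff(r1$params$omega) >= -1e-12))
  expect_lte(r1$params$omega[2], 1 + 1e-12)
  expect_gte(r1$params$omega[3], 1 - 1e-12)
  expect_equal(sum(r1$params$prop), 1, tolerance = 1e-12)
  # category proportions of the PDM each sum to 1
  expect_equal(sum(pdm$params$prop_ref), 1, tolerance = 1e-12)
  expect_equal(sum(pdm$params$prop_test), 1, tolerance = 1e-12)

  # omega = 1 category is a fixed point of the intensity map
  m_k <- model_relax(2, c(0.1, 1, 1.8), c(1 / 3, 1 / 3, 1 / 3), 0.17,
                     rep(1 / 61, 61))
  expect_equal(m_k$classes[[2]]$omega[["1"]], 1)
})

test_that("estimates converge toward the truth as alignments grow", {
  lt <- fixture_labeled_tree(6, absent = "sp2", reduced = NULL, height = 0.5,
                             seed = 29)
  err <- function(n_codons, seed) {
    aln <- simulate_codon_alignment(lt, "m0", list(kappa = 2, omega = 0.3),
                                    n_codons, seed)
    og <- orthogroup("cv", aln, lt)
    abs(fit_single_omega(og)$params$omega - 0.3)
  }
  pairs <- vapply(1:5, function(i) {
    c(short = err(100, 300 + i), long = err(1000, 400 + i))
  }, numeric(2))
  # absolute error shrinks with alignment length in most paired replicates
  expect_gte(mean(pairs["long", ] < pairs["short", ]), 0.8)
})
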