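test_that("the codon generator has GY94 structure, zero row sums and
           detailed balance", {
  set.seed(2)
  for (i in 1:3) {
    kappa <- runif(1, 0.5, 5); omega <- runif(1, 0.05, 2)
    pi <- as.numeric(prop.table(runif(61, 0.5, 1.5)))
    Q <- build_rate_matrix(kappa, omega, pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # time reversibility: pi_i q_ij = pi_j q_ji
    B <- diag(pi) %*% Q
    expect_lt(max(abs(B - t(B))), 1e-12)
    # unit expected substitution rate at equilibrium
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  }

  # multi-nucleotide changes are forbidden
  Q <- build_rate_matrix(2, 0.5, rep(1 / 61, 61))
  code <- genetic_code()
  spl <- do.call(rbind, strsplit(code$sense_codons, ""))
  ndiff <- function(i, j) sum(spl[i, ] != spl[j, ])
  for (pair in list(c(1, 10), c(5, 40), c(2, 61))) {
    if (ndiff(pair[1], pair[2]) > 1) expect_equal(Q[pair[1], pair[2]], 0)
  }
})

test_that("with uniform frequencies, kappa=1, omega=1 all allowed rates are
           equal and match the hand-computed scaling", {
  pi <- rep(1 / 61, 61)
  Q <- build_rate_matrix(1, 1, pi)
  off <- Q[row(Q) != col(Q)]
  vals <- unique(round(off[off > 0], 14))
  expect_length(vals, 1L)
  # hand computation: before scaling every allowed rate is 1/61 and each row
  # has n_i single-nucleotide sense neighbours, so the equilibrium rate is
  # mean(n_i)/61; scaling makes each allowed rate (1/61)/(mean(n_i)/61)
  st <- selcontrast:::.q_structure()
  n_nb <- tabulate(st$i, nbins = 61)
  expect_equal(vals, (1 / 61) / (mean(n_nb) / 61), tolerance = 1e-12)
})

test_that("transition probabilities behave as a stochastic semigroup", {
  pi <- as.numeric(prop.table(runif(61, 0.5, 1.5)))
  Q <- build_rate_matrix(2, 0.3, pi)
  P0 <- transition_probabilities(Q, 0)
  expect_equal(P0, diag(61), ignore_attr = TRUE, tolerance = 1e-12)

  P1 <- transition_probabilities(Q, 0.3)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  expect_true(all(P1 >= 0))

  # ergodic limit: every row converges to pi
  Pinf <- transition_probabilities(Q, 100)
  expect_lt(max(abs(sweep(Pinf, 2, pi))), 1e-6)

  # semigroup property P(t1) P(t2) = P(t1 + t2)
  P2 <- transition_probabilities(Q, 0.5)
  P12 <- transition_probabilities(Q, 0.8)
  expect_lt(max(abs(P1 %*% P2 - P12)), 1e-8)

  expect_error(transition_probabilities(Q, -1), ">= 0")
})

test_that("F3x4 frequencies are positive, normalised and match the direct
           product formula", {
  lt <- fixture_labeled_tree(5, absent = "sp2", reduced = NULL)
  aln <- simulate_codon_alignment(lt, "m0", list(kappa = 2, omega = 0.3),
                                  100, seed = 4)
  pi <- estimate_f3x4(aln)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_true(all(pi > 0))

  # direct empirical product on a tiny 3-sequence fixture
  aln3 <- codon_alignment(c(a = "ATGAAA", b = "ATGCCC", c = "TTGAAA"))
  pi3 <- estimate_f3x4(aln3)
  m <- unclass(aln3)
  codons <- as.vector(m)
  nts <- c("A", "C", "G", "T")
  freq <- sapply(1:3, function(p) {
    (table(factor(substring(codons, p, p), levels = nts)) + 0.5) /
      (length(codons) + 2)
  })
  code <- genetic_code()
  byhand <- vapply(code$sense_codons, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    freq[ch[1], 1] * freq[ch[2], 2] * freq[ch[3], 3]
  }, numeric(1))
  byhand <- byhand / sum(byhand)
  expect_equal(as.numeric(pi3), as.numeric(byhand), tolerance = 1e-12)

  # an alignment using all nucleotides uniformly gives near-uniform pi
  unif <- codon_alignment(c(a = "ACGTACGTACGT", b = "CATGCATGCATG"))
  piu <- estimate_f3x4(unif)
  expect_lt(max(abs(piu - 1 / 61)), 0.005)
})

test_that("pruning log-likelihood equals brute-force enumeration for every
           implemented model family", {
  set.seed(13)
  tr <- ape::read.tree(text = "((a:0.15,b:0.25):0.1,c:0.3);")
  lt <- labeled_tree(tr, c(a = "present", b = "absent", c = "reduced"))
  pi <- as.numeric(prop.table(runif(61, 0.8, 1.2)))
  aln <- simulate_codon_alignment(
    lt, "branch3",
    list(kappa = 2, omegas = c("0" = 0.2, "1" = 0.5, "2" = 1.2), pi = pi),
    6, seed = 14)
  # inject a missing codon to exercise the missing-state path
  m <- unclass(aln); m["b", 2] <- "---"
  aln <- codon_alignment(m)
  models <- list(
    m0 = model_m0(1.7, 0.35, pi),
    branch3 = model_branch(2.2, c("0" = 0.1, "1" = 0.6, "2" = 1.5), pi),
    modelA = model_a(1.9, 0.15, 3.0, 0.55, 0.3, pi)
  )
  lt2 <- label_contrast(lt, "absent")
  for (nm in names(models)) {
    use_lt <- if (nm == "modelA") lt2 else lt
    got <- log_likelihood(aln, use_lt, models[[nm]], scale = 0.9)
    want <- brute_force_loglik(aln, use_lt, models[[nm]], scale = 0.9)
    expect_equal(got, want, tolerance = 1e-8, label = paste("lnL", nm))
  }

  # RELAX-style branch random effects against the explicit-kernel oracle
  mrx <- model_relax(2.1, c(0.05, 0.6, 1.4), c(0.5, 0.3, 0.2), 0.4, pi)
  got <- log_likelihood(aln, lt2, mrx, scale = 0.9)
  want <- brute_force_loglik_branchmix(aln, lt2, mrx, scale = 0.9)
  expect_equal(got, want, tolerance = 1e-8)

  mpdm <- model_pdm(2.1, c(0.05, 0.6, 1.4), c(0.5, 0.3, 0.2),
                    c(0.2, 0.9, 2.0), c(0.3, 0.4, 0.3), pi)
  got <- log_likelihood(aln, lt2, mpdm, scale = 0.9)
  want <- brute_force_loglik_branchmix(aln, lt2, mpdm, scale = 0.9)
  expect_equal(got, want, tolerance = 1e-8)

  # 4-taxon star (single internal node): branch models again
  tr4 <- ape::read.tree(text = "(a:0.1,b:0.2,c:0.15,d:0.25);")
  lt4 <- labeled_tree(tr4, c(a = "present", b = "absent", c = "reduced",
                             d = "present"))
  aln4 <- simulate_codon_alignment(lt4, "m0", list(kappa = 2, omega = 0.3,
                                                   pi = pi), 5, seed = 15)
  for (mod in list(model_m0(2.4, 0.25, pi),
                   model_branch(1.5, c("0" = 0.3, "1" = 0.9, "2" = 2.1), pi))) {
    expect_equal(log_likelihood(aln4, lt4, mod),
                 brute_force_loglik(aln4, lt4, mod), tolerance = 1e-8)
  }
})

test_that("degenerate cases and invariances of the likelihood", {
  # two identical sequences joined by zero-length branches:
  # lnL = sum_sites log pi(codon)
  tr <- ape::read.tree(text = "(a:0,b:0);")
  lt <- labeled_tree(tr)
  aln <- codon_alignment(c(a = "ATGAAACCC", b = "ATGAAACCC"))
  pi <- as.numeric(prop.table(runif(61, 0.5, 1.5)))
  got <- log_likelihood(aln, lt, model_m0(2, 0.5, pi))
  idx <- genetic_code()$codon_index[c("ATG", "AAA", "CCC")]
  expect_equal(got, sum(log(pi[idx])), tolerance = 1e-10)

  # invariance under site-column permutation (pattern compression)
  lt8 <- fixture_labeled_tree(8)
  big <- simulate_codon_alignment(lt8, "m0", list(kappa = 2, omega = 0.2),
                                  60, seed = 5)
  model <- model_m0(2, 0.2, rep(1 / 61, 61))
  l1 <- log_likelihood(big, lt8, model)
  perm <- codon_alignment(unclass(big)[, sample(60)])
  expect_equal(log_likelihood(perm, lt8, model), l1, tolerance = 1e-10)

  # missing data: a fully ambiguous column contributes zero information and
  # factors out of the likelihood
  m <- unclass(big)[, 1:10]
  m2 <- cbind(m, "---")
  l_a <- log_likelihood(codon_alignment(m), lt8, model)
  l_b <- log_likelihood(codon_alignment(m2), lt8, model)
  expect_equal(l_b, l_a, tolerance = 1e-8)
})
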