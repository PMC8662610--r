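test_that("the likelihood-ratio test uses the chi-square survival function", {
  t0 <- lrt(-100, -100, 2)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)

  # statistic 6 with 2 df: survival is exp(-x/2) = exp(-3)
  t1 <- lrt(-103, -100, 2)
  expect_equal(t1$statistic, 6)
  expect_equal(t1$p, exp(-3), tolerance = 1e-12)

  expect_error(lrt(-1, -1, 0), "df")
  # tiny negative statistics from numerical noise are clipped
  expect_equal(lrt(-100, -100.000001, 2)$statistic, 0)
})

test_that("q-values match Benjamini-Hochberg at pi0 = 1 and stay below the
           pi0 estimate", {
  expect_warning(q_all1 <- qvalues(rep(1, 5)), "fewer than 10")
  expect_equal(q_all1$qvalues, rep(1, 5))

  set.seed(31)
  p <- c(runif(500), rbeta(500, 0.1, 8))
  q_forced <- qvalues(p, pi0 = 1)
  expect_equal(q_forced$qvalues, p.adjust(p, "BH"), tolerance = 1e-12)

  q <- qvalues(p)
  expect_true(all(q$qvalues <= q$pi0 + 1e-12))
  # q monotone in p
  ord <- order(p)
  expect_true(all(diff(q$qvalues[ord]) >= -1e-12))

  # pi0 recovery on a 50:50 uniform/near-zero mixture
  pi0s <- vapply(1:10, function(s) {
    set.seed(s)
    mix <- c(runif(500), rbeta(500, 0.05, 20))
    qvalues(mix)$pi0
  }, numeric(1))
  expect_true(all(pi0s > 0.3 & pi0s < 0.7))
  # bootstrap variant agrees broadly with the smoother
  set.seed(1)
  mix <- c(runif(500), rbeta(500, 0.05, 20))
  expect_lt(abs(qvalues(mix, method = "bootstrap")$pi0 - qvalues(mix)$pi0), 0.2)
})

test_that("Kruskal-Wallis matches the hand-rank formula and a permutation
           null", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 3)))$p, 1)

  # hand computation for {1,2,3} vs {4,5,6}: rank sums 6 and 15,
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  g <- list(c(1, 2, 3), c(4, 5, 6))
  H_hand <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(kruskal_wallis(g)$statistic, H_hand, tolerance = 1e-12)

  # chi-square p is close to the permutation p on a larger fixture
  set.seed(32)
  x <- list(rnorm(12), rnorm(12, 1), rnorm(12, 0.5))
  obs <- kruskal_wallis(x)
  pool <- unlist(x)
  lens <- lengths(x)
  perm <- replicate(2000, {
    sh <- sample(pool)
    kruskal_wallis(split(sh, rep(seq_along(lens), lens)))$statistic
  })
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(p_perm - obs$p), 0.03)
})

test_that("the all-pairs post-hoc test is symmetric, bounded and consistent
           with pairwise rank tests", {
  same <- list(a = c(1, 2, 3, 4), b = c(1.1, 2.1, 2.9, 4.1),
               c = c(0.9, 1.9, 3.1, 3.9))
  P <- dscf_posthoc(same)
  expect_true(isSymmetric(P))
  expect_true(all(P[upper.tri(P)] >= 0 & P[upper.tri(P)] <= 1))
  expect_false(any(P[upper.tri(P)] < 0.05))

  set.seed(33)
  g <- list(a = rnorm(15), b = rnorm(15, 2), c = rnorm(15, 0.3))
  P2 <- dscf_posthoc(g)
  w_ab <- wilcox.test(g$a, g$b)$p.value
  w_ac <- wilcox.test(g$a, g$c)$p.value
  # more separated pair has the smaller p in both procedures
  expect_true((P2["a", "b"] < P2["a", "c"]) == (w_ab < w_ac))
  expect_error(dscf_posthoc(same[1:2]), "3")
})

test_that("chi-square against expected annotation-group proportions matches
           the published table-derived statistics", {
  totals_pa <- c(503, 116, 95, 231)
  t1 <- chi_square_expected(c(38, 6, 9, 11), totals_pa)
  expect_equal(t1$statistic, 3.3, tolerance = 0.05)
  expect_equal(t1$df, 3L)
  expect_equal(t1$p, 0.35, tolerance = 0.01)

  t2 <- chi_square_expected(c(209, 22, 17, 55), totals_pa)
  expect_equal(t2$statistic, 31.2, tolerance = 0.05)

  # observed proportional to totals -> statistic 0, p 1
  t3 <- chi_square_expected(c(50, 10, 20), c(500, 100, 200))
  expect_equal(t3$statistic, 0, tolerance = 1e-12)
  expect_equal(t3$p, 1)
  expect_error(chi_square_expected(c(0, 0), c(10, 10)), "no significant")
})

test_that("omega patterns classify exhaustively and break ties upward", {
  expect_equal(classify_omega_pattern(0.1, 0.2, 0.3)[c("coarse", "fine")],
               list(coarse = "+", fine = "+/+"))
  expect_equal(classify_omega_pattern(0.3, 0.1, 0.2)[c("coarse", "fine")],
               list(coarse = "-", fine = "-/+"))
  tie <- classify_omega_pattern(0.2, 0.2, 0.4)
  expect_true(tie$tie)
  expect_equal(tie$fine, "+/+")

  set.seed(34)
  fine_levels <- c("-/-", "-/+", "+/-", "+/+")
  for (i in 1:200) {
    w <- runif(3, 0.01, 2)
    cls <- classify_omega_pattern(w[1], w[2], w[3])
    expect_true(cls$coarse %in% c("-", "+"))
    expect_true(cls$fine %in% fine_levels)
  }
})

test_that("independent transition counts match brute-force path enumeration", {
  lt <- fixture_labeled_tree(12, absent = c("sp2", "sp5", "sp9"),
                             reduced = c("sp3", "sp7"), seed = 35)
  for (tip in c("sp2", "sp5", "sp9")) lt <- mark_transition(lt, tip, "loss")
  for (tip in c("sp3", "sp7")) lt <- mark_transition(lt, tip, "reduction")

  # one hypodermic tip -> exactly its own loss branch
  expect_equal(count_independent_transitions(c("sp1", "sp2"), lt, "loss"), 1L)
  # no absent-state taxon -> zero
  expect_equal(count_independent_transitions(c("sp1", "sp4"), lt, "loss"), 0L)
  expect_equal(count_independent_transitions(lt$tree$tip.label, lt, "loss"), 3L)
  expect_equal(count_independent_transitions(lt$tree$tip.label, lt, "reduction"), 2L)
  expect_error(count_independent_transitions("nope", lt, "loss"), "nope")

  # brute force: walk root-to-tip paths and collect marked branches
  set.seed(36)
  brute <- function(taxa, event) {
    derived <- c(loss = "absent", reduction = "reduced")[[event]]
    marks <- lt$transitions[lt$transitions$event == event, "node"]
    hit <- logical(length(marks))
    for (tx in taxa) {
      if (lt$tip_states[[tx]] != derived) next
      nd <- match(tx, lt$tree$tip.label)
      path <- nd
      while (TRUE) {
        e <- match(nd, lt$tree$edge[, 2])
        if (is.na(e)) break
        nd <- lt$tree$edge[e, 1]
        path <- c(path, nd)
      }
      hit <- hit | marks %in% path
    }
    sum(hit)
  }
  for (i in 1:20) {
    taxa <- sample(lt$tree$tip.label, sample(2:10, 1))
    for (ev in c("loss", "reduction")) {
      expect_equal(count_independent_transitions(taxa, lt, ev), brute(taxa, ev))
    }
  }
})

test_that("codon-usage bias B matches hand computations", {
  # identical usage -> 0
  g <- c(AAA = 10, AAG = 5, TTT = 3)
  expect_equal(codon_usage_bias_b(g, g * 7), 0)

  # maximal divergence in a 2-codon family, single amino acid -> B = 2
  expect_equal(codon_usage_bias_b(c(AAA = 12), c(AAG = 40)), 2)

  # hand-computed 3-amino-acid fixture:
  # gene: Lys AAA 6 / AAG 2 (f = 8/14), Phe TTT 4 (f = 4/14, ref split),
  # Met ATG 2 (single-codon family, contributes 0)
  gene <- c(AAA = 6, AAG = 2, TTT = 4, ATG = 2)
  ref <- c(AAA = 10, AAG = 10, TTT = 5, TTC = 5, ATG = 3)
  b_hand <- (8 / 14) * (abs(6 / 8 - 0.5) + abs(2 / 8 - 0.5)) +
    (4 / 14) * (abs(1 - 0.5) + abs(0 - 0.5))
  expect_equal(codon_usage_bias_b(gene, ref), b_hand, tolerance = 1e-12)

  expect_error(codon_usage_bias_b(c(AAA = 0), ref), "empty")
  expect_error(codon_usage_bias_b(c(GGG = 3), c(AAA = 5)), "reference")
})

test_that("Spearman correlation handles monotone, reversed and exact cases", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(spearman(x, x * 2 + 1)$statistic, 1)
  expect_equal(spearman(x, rev(x))$statistic, -1)
  expect_error(spearman(rep(1, 5), x[1:5]), "zero variance")

  # small-n exact test: p matches the exhaustive permutation distribution
  set.seed(37)
  y <- rnorm(8)
  x6 <- x[1:6]; y6 <- y[1:6]
  got6 <- spearman(x6, y6)
  perm_idx <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perm_idx <- perm_idx[apply(perm_idx, 1, function(r) length(unique(r)) == 6L), ]
  rhos <- apply(perm_idx, 1, function(ix) cor(x6, y6[ix], method = "spearman"))
  p_ex <- mean(abs(rhos) >= abs(cor(x6, y6, method = "spearman")) - 1e-12)
  expect_equal(got6$p, p_ex, tolerance = 1e-10)
})
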