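# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdirs.

# small ultrametric tree with named tips sp1..spN, height scaled to `height`
fixture_tree <- function(n, height = 0.5, seed = 1) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * height
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

# labeled tree with a few absent/reduced tips
fixture_labeled_tree <- function(n = 8, absent = c("sp2", "sp5"),
                                 reduced = "sp3", height = 0.5, seed = 1) {
  tr <- fixture_tree(n, height, seed)
  states <- setNames(rep("present", n), tr$tip.label)
  states[absent] <- "absent"
  states[reduced] <- "reduced"
  labeled_tree(tr, states)
}

fixture_orthogroup <- function(lt, regime = "m0",
                               params = list(kappa = 2, omega = 0.2),
                               n_codons = 200, seed = 1, og_id = "og1") {
  aln <- simulate_codon_alignment(lt, regime, params, n_codons, seed)
  orthogroup(og_id, aln, lt)
}

# equilibrium rate of the unnormalised GY94 generator, from first principles
# (used to reproduce the common mixture scaling in the oracles)
brute_rate <- function(kappa, omega, pi) {
  code <- genetic_code()
  sense <- code$sense_codons
  spl <- do.call(rbind, strsplit(sense, ""))
  aa <- code$codon_to_aa[sense]
  ts_pairs <- c("AG", "GA", "CT", "TC")
  r <- 0
  for (i in 1:61) for (j in 1:61) {
    if (i == j) next
    d <- which(spl[i, ] != spl[j, ])
    if (length(d) != 1L) next
    rate <- pi[i] * pi[j] *
      (if (paste0(spl[i, d], spl[j, d]) %in% ts_pairs) kappa else 1) *
      (if (aa[i] == aa[j]) 1 else omega)
    r <- r + rate
  }
  r
}

# per-class relative branch-length multiplier under common mixture scaling
brute_rate_mult <- function(model) {
  rates <- vapply(model$classes, function(cl) {
    brute_rate(model$kappa, cl$omega[["0"]], model$pi)
  }, numeric(1))
  props <- vapply(model$classes, function(cl) {
    if (!is.null(cl$prop_by_partition)) cl$prop_by_partition[["0"]] else cl$prop
  }, numeric(1))
  f <- sum(props * rates)
  function(omega) brute_rate(model$kappa, omega, model$pi) / f
}

# brute-force log-likelihood by enumeration over internal-node states, for
# site-shared mixture models (independent of the pruning implementation)
brute_force_loglik <- function(aln, lt, model, scale = 1) {
  tr <- lt$tree
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  code <- genetic_code()
  st <- matrix(0L, ntip, ncol(aln))
  m <- unclass(aln)
  for (i in seq_len(ntip)) {
    row <- m[tr$tip.label[i], ]
    st[i, ] <- ifelse(row %in% code$sense_codons, code$codon_index[row], 0L)
  }
  lab_by_child <- integer(nnode)
  lab_by_child[tr$edge[, 2]] <- lt$branch_labels
  internals <- (ntip + 1L):nnode
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internals))))
  mult <- brute_rate_mult(model)
  total <- 0
  for (s in seq_len(ncol(aln))) {
    site_lik <- 0
    for (cl in model$classes) {
      if (cl$prop <= 0) next
      Ps <- list()
      for (e in seq_len(nrow(tr$edge))) {
        om <- cl$omega[[as.character(lab_by_child[tr$edge[e, 2]])]]
        Q <- build_rate_matrix(model$kappa, om, model$pi)
        Ps[[e]] <- transition_probabilities(Q, tr$edge.length[e] * scale * mult(om))
      }
      lik_c <- 0
      root <- ntip + 1L
      for (g in seq_len(nrow(grid))) {
        assign_state <- integer(nnode)
        assign_state[internals] <- grid[g, ]
        prob <- model$pi[assign_state[root]]
        ok <- TRUE
        for (e in seq_len(nrow(tr$edge))) {
          p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
          chs <- if (ch <= ntip) st[ch, s] else assign_state[ch]
          if (chs == 0L) next  # missing tip: sums over all states = row sum 1
          prob <- prob * Ps[[e]][assign_state[p], chs]
          if (prob == 0) { ok <- FALSE; break }
        }
        if (ok) lik_c <- lik_c + prob
      }
      site_lik <- site_lik + cl$prop * lik_c
    }
    total <- total + log(site_lik)
  }
  total
}

# brute force for branch-mixture (random-effects) models: the per-edge kernel
# is formed explicitly as the weighted sum of category matrices
brute_force_loglik_branchmix <- function(aln, lt, model, scale = 1) {
  tr <- lt$tree
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  code <- genetic_code()
  m <- unclass(aln)
  st <- matrix(0L, ntip, ncol(aln))
  for (i in seq_len(ntip)) {
    row <- m[tr$tip.label[i], ]
    st[i, ] <- ifelse(row %in% code$sense_codons, code$codon_index[row], 0L)
  }
  lab_by_child <- integer(nnode)
  lab_by_child[tr$edge[, 2]] <- lt$branch_labels
  mult <- brute_rate_mult(model)
  Ps <- list()
  for (e in seq_len(nrow(tr$edge))) {
    lab <- as.character(lab_by_child[tr$edge[e, 2]])
    Pe <- matrix(0, 61, 61)
    for (cl in model$classes) {
      w <- if (!is.null(cl$prop_by_partition)) cl$prop_by_partition[[lab]] else cl$prop
      Q <- build_rate_matrix(model$kappa, cl$omega[[lab]], model$pi)
      Pe <- Pe + w * transition_probabilities(
        Q, tr$edge.length[e] * scale * mult(cl$omega[[lab]]))
    }
    Ps[[e]] <- Pe
  }
  internals <- (ntip + 1L):nnode
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internals))))
  total <- 0
  root <- ntip + 1L
  for (s in seq_len(ncol(aln))) {
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- integer(nnode)
      assign_state[internals] <- grid[g, ]
      prob <- model$pi[assign_state[root]]
      for (e in seq_len(nrow(tr$edge))) {
        ch <- tr$edge[e, 2]
        chs <- if (ch <= ntip) st[ch, s] else assign_state[ch]
        if (chs == 0L) next
        prob <- prob * Ps[[e]][assign_state[tr$edge[e, 1]], chs]
        if (prob == 0) break
      }
      lik <- lik + prob
    }
    total <- total + log(lik)
  }
  total
}
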