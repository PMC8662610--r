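#' Design of a synthetic comparative study
#'
#' Collects every knob of the synthetic-data generator: the species sample,
#' the number of phylogenetically independent trait transitions, orthogroup
#' counts per annotation group, the group- and state-specific dN/dS
#' distributions, the selection-intensity exponent applied to absent-state
#' lineages, and alignment length. Defaults give a mini study (16 ingroup
#' species, 80 orthogroups, 300 codons) sized to run the full pipeline in
#' minutes on one CPU.
#'
#' dN/dS values are drawn per orthogroup and state from lognormal
#' distributions whose means encode the expected ordering: reproduction-
#' related groups above ubiquitously expressed ones, and absent > reduced >
#' present across bristle states.
#'
#' @param n_species Ingroup species count (default 16).
#' @param n_outgroup Outgroup species count (default 2).
#' @param n_losses Independent losses placed on the tree (default 3).
#' @param n_reductions Independent reductions (default 2).
#' @param n_ogs Named integer vector of orthogroups per annotation group.
#' @param omega_means Base mean dN/dS per annotation group (present state).
#' @param state_multipliers Multiplier per bristle state.
#' @param omega_sdlog Lognormal sd (log scale) of per-orthogroup dN/dS.
#' @param kappa Transition/transversion ratio used in simulation.
#' @param relax_k Selection-intensity exponent applied to absent-state
#'   branches (1 = no intensity shift; < 1 relaxes selection).
#' @param n_codons Codons per alignment (default 300).
#' @param dup_rate,loss_rate Homolog-tree duplication/loss rates per unit
#'   branch length.
#' @param taxon_sampling Range of the fraction of ingroup species present per
#'   orthogroup.
#' @param low_score_frac Fraction of low-reliability (score <= 3) columns.
#' @param gap_frac Fraction of codons replaced by gaps per alignment.
#' @param expr_rho Target Spearman correlation between expression level and
#'   per-orthogroup dN/dS (negative: highly expressed genes evolve slowly).
#' @param seed Integer seed; every generator output is reproducible from
#'   (design, seed).
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_species = 16L, n_outgroup = 2L, n_losses = 3L,
                         n_reductions = 2L,
                         n_ogs = c("testis-region" = 40L, "ovary-region" = 10L,
                                   "tail-region" = 10L, "ubiquitous" = 20L),
                         omega_means = c("testis-region" = 0.20,
                                         "ovary-region" = 0.18,
                                         "tail-region" = 0.18,
                                         "ubiquitous" = 0.10),
                         state_multipliers = c(present = 1, reduced = 1.4,
                                               absent = 1.8),
                         omega_sdlog = 0.4, kappa = 2, relax_k = 1,
                         n_codons = 300L, dup_rate = 0, loss_rate = 0,
                         taxon_sampling = c(0.7, 1), low_score_frac = 0.1,
                         gap_frac = 0.03, expr_rho = -0.6, seed = 1L) {
  stopifnot(n_species >= 4L, n_outgroup >= 1L, all(n_ogs >= 1L),
            all(omega_means > 0), n_codons >= 10L, relax_k > 0)
  structure(as.list(environment()), class = "study_design")
}

#' Simulate a species tree with labelled trait transitions
#'
#' A pure-birth ingroup tree scaled to height 1 with a basally attached
#' outgroup clade. Loss and reduction transition marks are placed on
#' non-nested ingroup branches (small clades preferred so that the ancestral
#' present state stays in the majority) and the derived state is propagated
#' tipward.
#'
#' @param design A [study_design()].
#' @return A [labeled_tree()]; ingroup tips are `sp01`, `sp02`, ..., outgroup
#'   tips `out1`, ....
#' @export
simulate_species_tree <- function(design) {
  set.seed(design$seed)
  n <- design$n_species
  ing <- ape::rphylo(n, birth = 1, death = 0)
  ing$tip.label <- sprintf("sp%02d", seq_len(n))
  depth <- max(ape::node.depth.edgelength(ing))
  ing$edge.length <- ing$edge.length / depth
  out_str <- if (design$n_outgroup == 1L) {
    "out1:0.3"
  } else {
    og <- ape::rphylo(design$n_outgroup, birth = 1, death = 0)
    og$tip.label <- paste0("out", seq_len(design$n_outgroup))
    og$edge.length <- og$edge.length / max(ape::node.depth.edgelength(og)) * 0.3
    sub(";$", "", ape::write.tree(og))
  }
  ing_str <- sub(";$", "", ape::write.tree(ing))
  tr <- ape::read.tree(text = paste0("(", ing_str, ":0.25,", out_str, ":0.25);"))

  # candidate branches for transitions: ingroup edges whose clade holds at
  # most a quarter of the ingroup (and no outgroup tips)
  ntip <- length(tr$tip.label)
  sets <- .node_tipsets(tr)
  ing_tips <- grep("^sp", tr$tip.label, value = TRUE)
  clade_tips <- lapply(tr$edge[, 2], function(nd) tr$tip.label[sets[[nd]]])
  ok <- vapply(clade_tips, function(x) {
    all(grepl("^sp", x)) && length(x) <= max(1L, floor(n / 4))
  }, logical(1))
  cand <- which(ok)
  cand <- cand[sample.int(length(cand))]
  # prefer small clades so that marks fit and present tips stay the majority
  cand <- cand[order(lengths(clade_tips[cand]))]
  n_marks <- design$n_losses + design$n_reductions
  chosen <- integer(0)
  taken <- character(0)
  for (e in cand) {
    if (length(chosen) == n_marks) break
    tips <- clade_tips[[e]]
    if (length(intersect(tips, taken))) next
    # keep a majority of present-state ingroup tips
    if (length(taken) + length(tips) > floor(n / 2)) next
    chosen <- c(chosen, e)
    taken <- union(taken, tips)
  }
  if (length(chosen) < n_marks) {
    stop("transitions exceed available non-nested branches")
  }
  events <- rep(c("loss", "reduction"),
                c(design$n_losses, design$n_reductions))
  states <- setNames(rep("present", ntip), tr$tip.label)
  lt <- labeled_tree(tr)
  derived <- c(loss = "absent", reduction = "reduced")
  for (i in seq_along(chosen)) {
    tips <- clade_tips[[chosen[i]]]
    states[tips] <- derived[[events[i]]]
    lt <- mark_transition(labeled_tree(tr, states, lt$transitions), tips,
                          events[i])
  }
  labeled_tree(tr, states, lt$transitions)
}

# cache of spectral decompositions within one simulation call
.sim_P <- function(cache, kappa, omega, pi, t) {
  key <- paste(signif(omega, 12), signif(t, 12))
  if (!is.null(cache[[key]])) return(cache[[key]])
  ekey <- paste0("e", signif(omega, 12))
  ed <- cache[[ekey]]
  if (is.null(ed)) {
    Q <- build_rate_matrix(kappa, omega, pi)
    ed <- .eigen_q(Q, pi)
    cache[[ekey]] <- ed
  }
  P <- ed$U %*% (exp(ed$lambda * t) * ed$Uinv)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  cache[[key]] <- P
  P
}

#' Simulate a codon alignment along a labelled tree
#'
#' Root codons are drawn from the equilibrium distribution and evolved along
#' each branch by sampling from the transition probabilities of the regime's
#' rate matrices; branch lengths are interpreted as expected substitutions
#' per codon. For mixture regimes the site class is drawn once per site and
#' recorded as ground truth in the attribute `site_classes`.
#'
#' @param lt A [labeled_tree()] (its `branch_labels` select each branch's
#'   partition).
#' @param regime `"m0"`, `"branch3"`, `"modelA"` or `"relax"`.
#' @param params Named list: `kappa`, plus `omega` (m0), `omegas` (branch3:
#'   named by partition `"0"`,`"1"`,`"2"`), `w0`/`w2`/`p0`/`p1` (modelA), or
#'   `w`/`p`/`k` (relax). Optional `pi` (default uniform over 61).
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @return A [codon_alignment()] with attributes `site_classes` and
#'   `true_params`.
#' @export
simulate_codon_alignment <- function(lt, regime = c("m0", "branch3", "modelA",
                                                    "relax"),
                                     params, n_codons, seed = 1L) {
  regime <- match.arg(regime)
  set.seed(seed)
  pi <- params$pi
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  model <- switch(regime,
    m0 = model_m0(params$kappa, params$omega, pi),
    branch3 = model_branch(params$kappa, params$omegas, pi),
    modelA = model_a(params$kappa, params$w0, params$w2, params$p0,
                     params$p1, pi),
    relax = model_relax(params$kappa, params$w, params$p, params$k, pi))
  props <- vapply(model$classes, `[[`, numeric(1), "prop")
  # for site-shared mixtures the class is drawn once per site and recorded as
  # ground truth; the RELAX-style regime draws the category independently per
  # branch and site (branch-site random effects)
  per_branch <- identical(model$sharing, "branch")
  classes <- sample.int(length(props), n_codons, replace = TRUE, prob = props)

  tr <- ape::reorder.phylo(lt$tree, "postorder")
  lab_by_child <- integer(length(tr$tip.label) + tr$Nnode)
  lab_by_child[lt$tree$edge[, 2]] <- lt$branch_labels
  co <- .rate_coeffs(params$kappa, pi)
  f <- .mixture_scale(model, co)
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  nnode <- ntip + tr$Nnode
  states <- matrix(0L, nnode, n_codons)
  states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  cache <- new.env(parent = emptyenv())
  for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    elab <- as.character(lab_by_child[child])
    ecl <- if (per_branch) {
      sample.int(length(props), n_codons, replace = TRUE, prob = props)
    } else classes
    for (ci in unique(ecl)) {
      om <- model$classes[[ci]]$omega[[elab]]
      t_eff <- tr$edge.length[e] * (co[["a"]] + co[["b"]] * om) / f
      P <- .sim_P(cache, params$kappa, om, pi, t_eff)
      idx <- which(ecl == ci)
      states[child, idx] <- evolve_states_cpp(states[parent, idx], P,
                                              runif(length(idx)))
    }
  }
  sense <- genetic_code()$sense_codons
  m <- matrix(sense[states[seq_len(ntip), , drop = FALSE]], ntip, n_codons,
              dimnames = list(tr$tip.label, NULL))
  aln <- codon_alignment(m)
  attr(aln, "site_classes") <- if (per_branch) NULL else classes
  attr(aln, "true_params") <- params
  aln
}

#' Simulate a homolog gene tree within a species tree
#'
#' Gene lineages evolve down the rooted species tree with Poisson
#' duplications and losses (rates per unit branch length). Tips are labelled
#' `species@t<i>`; the true ortholog partition (tips descending from a single
#' ancestral gene copy, i.e. sharing a locus) and per-tip aligned-column
#' counts (uniform on 100-400) are recorded as attributes.
#'
#' @param species_lt A [labeled_tree()] species tree.
#' @param dup_rate,loss_rate Event rates (>= 0) per unit branch length.
#' @param seed Integer seed.
#' @return A [homolog_tree()] with attributes `true_orthologs` (list of tip
#'   sets by locus) or `NULL` if all lineages were lost in 10 attempts.
#' @export
simulate_homolog_tree <- function(species_lt, dup_rate = 0.1, loss_rate = 0.05,
                                  seed = 1L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  set.seed(seed)
  tr <- species_lt$tree
  ntip <- length(tr$tip.label)
  kids_of <- function(nd) tr$edge[tr$edge[, 1] == nd, 2]
  elen_of <- function(nd) tr$edge.length[match(nd, tr$edge[, 2])]

  for (attempt in 1:10) {
    env <- new.env()
    env$locus <- 1L
    env$tipn <- integer(ntip)
    # returns list(str = newick fragment without stem, stem = stem length,
    # tips = tip labels, locus per tip) or NULL if lineage extinct
    descend <- function(sp_node, offset, locus) {
      len <- elen_of(sp_node)
      rem <- len - offset
      t_dup <- if (dup_rate > 0) rexp(1, dup_rate) else Inf
      t_loss <- if (loss_rate > 0) rexp(1, loss_rate) else Inf
      if (min(t_dup, t_loss) < rem) {
        if (t_loss <= t_dup) return(NULL)
        # duplication: the new copy starts a fresh locus
        env$locus <- env$locus + 1L
        new_locus <- env$locus
        a <- descend(sp_node, offset + t_dup, locus)
        b <- descend(sp_node, offset + t_dup, new_locus)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a) || is.null(b)) {
          s <- if (is.null(a)) b else a
          s$stem <- s$stem + t_dup
          return(s)
        }
        return(list(str = paste0("(", a$str, ":", a$stem, ",", b$str, ":",
                                 b$stem, ")"),
                    stem = t_dup, tips = c(a$tips, b$tips),
                    loci = c(a$loci, b$loci)))
      }
      if (sp_node <= ntip) {
        env$tipn[sp_node] <- env$tipn[sp_node] + 1L
        lab <- paste0(tr$tip.label[sp_node], "@t", env$tipn[sp_node])
        return(list(str = lab, stem = rem, tips = lab, loci = locus))
      }
      kids <- kids_of(sp_node)
      subs <- lapply(kids, function(k) descend(k, 0, locus))
      subs <- Filter(Negate(is.null), subs)
      if (!length(subs)) return(NULL)
      if (length(subs) == 1L) {
        s <- subs[[1L]]
        s$stem <- s$stem + rem
        return(s)
      }
      inner <- paste0(vapply(subs, function(s) paste0(s$str, ":", s$stem),
                             character(1)), collapse = ",")
      list(str = paste0("(", inner, ")"), stem = rem,
           tips = unlist(lapply(subs, `[[`, "tips")),
           loci = unlist(lapply(subs, `[[`, "loci")))
    }
    root <- ntip + 1L
    kids <- kids_of(root)
    subs <- lapply(kids, function(k) descend(k, 0, 1L))
    subs <- Filter(Negate(is.null), subs)
    if (sum(lengths(lapply(subs, `[[`, "tips"))) >= 2L) {
      inner <- paste0(vapply(subs, function(s) paste0(s$str, ":", s$stem),
                             character(1)), collapse = ",")
      gt <- ape::read.tree(text = paste0(if (length(subs) == 1L)
        paste0(subs[[1L]]$str) else paste0("(", inner, ")"), ";"))
      tips <- unlist(lapply(subs, `[[`, "tips"))
      loci <- unlist(lapply(subs, `[[`, "loci"))
      ac <- setNames(sample(100:400, length(tips), replace = TRUE), tips)
      ht <- homolog_tree(gt, ac)
      attr(ht, "true_orthologs") <- unname(split(tips, loci))
      return(ht)
    }
  }
  warning("all gene lineages lost in 10 attempts")
  NULL
}

#' Generate a complete synthetic study on disk
#'
#' Writes everything the pipeline consumes: the species tree with trait and
#' transition annotations, one homolog tree plus amino-acid alignment, coding
#' sequences and column reliability scores per orthogroup, the annotation
#' table with expression levels, and a ground-truth manifest (true dN/dS per
#' orthogroup and state, the selection-intensity exponent, taxa and groups).
#'
#' @param design A [study_design()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
generate_study <- function(design, outdir) {
  dir.create(file.path(outdir, "ogs"), recursive = TRUE, showWarnings = FALSE)
  species_lt <- simulate_species_tree(design)
  set.seed(design$seed + 1L)
  tr <- species_lt$tree
  write_newick(tr, file.path(outdir, "species_tree.nwk"))
  write.table(data.frame(species = names(species_lt$tip_states),
                         state = unname(species_lt$tip_states)),
              file.path(outdir, "traits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  trans <- species_lt$transitions
  write.table(data.frame(
    event = trans$event,
    tips = vapply(trans$node, function(nd) {
      paste(.clade_tips(tr, nd), collapse = ",")
    }, character(1))),
    file.path(outdir, "transitions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- rep(names(design$n_ogs), design$n_ogs)
  n_og <- length(groups)
  og_ids <- sprintf("og%03d", seq_len(n_og))
  ing <- grep("^sp", tr$tip.label, value = TRUE)
  ref <- "sp01"
  states <- species_lt$tip_states

  manifest <- list(design = unclass(design), ogs = list())
  truth_omega <- matrix(NA_real_, n_og, 3,
                        dimnames = list(og_ids, c("present", "reduced", "absent")))
  ann <- data.frame(transcript = character(0), group = character(0),
                    expression = numeric(0))

  for (i in seq_len(n_og)) {
    gid <- og_ids[i]
    grp <- groups[i]
    base <- design$omega_means[[grp]]
    mult <- design$state_multipliers
    w <- vapply(c("present", "reduced", "absent"), function(st) {
      rlnorm(1, log(base * mult[[st]]) - design$omega_sdlog^2 / 2,
             design$omega_sdlog)
    }, numeric(1))
    truth_omega[i, ] <- w

    # taxon subset: always the reference species, plus enough of each state
    frac <- runif(1, design$taxon_sampling[1], design$taxon_sampling[2])
    keep <- unique(c(ref, sample(ing, max(4L, round(frac * length(ing))))))
    for (st in c("present", "reduced", "absent")) {
      st_tips <- ing[states[ing] == st]
      if (length(st_tips) && !any(keep %in% st_tips)) {
        keep <- c(keep, sample(st_tips, 1L))
      }
    }
    sub_lt <- prune_species_tree(species_lt, keep)

    if (design$relax_k != 1) {
      params <- list(kappa = design$kappa,
                     w = sort(c(w[["present"]] / 2, w[["present"]], 1.5)),
                     p = c(0.5, 0.4, 0.1), k = design$relax_k)
      sub2 <- label_contrast(sub_lt, "absent")
      aln <- simulate_codon_alignment(sub2, "relax", params, design$n_codons,
                                      seed = design$seed + 100L + i)
    } else {
      params <- list(kappa = design$kappa,
                     omegas = c("0" = unname(w[["present"]]),
                                "1" = unname(w[["reduced"]]),
                                "2" = unname(w[["absent"]])))
      aln <- simulate_codon_alignment(sub_lt, "branch3", params,
                                      design$n_codons,
                                      seed = design$seed + 100L + i)
    }

    # inject gaps, write amino-acid alignment + CDS + column scores
    m <- unclass(aln)
    if (design$gap_frac > 0) {
      ng <- round(design$gap_frac * length(m))
      # never gap the first taxon row completely; spread gaps at random
      pos <- sample(length(m), ng)
      m[pos] <- "---"
    }
    rownames(m) <- ifelse(rownames(m) == ref, paste0(ref, "@", gid),
                          paste0(rownames(m), "@t1"))
    aa <- apply(m, 1L, function(r) {
      paste(ifelse(r == "---", "-", translate_codons(r)), collapse = "")
    })
    cds <- apply(m, 1L, function(r) paste(r[r != "---"], collapse = ""))
    write_fasta(aa, file.path(outdir, "ogs", paste0(gid, ".aa.fasta")))
    write_fasta(cds, file.path(outdir, "ogs", paste0(gid, ".cds.fasta")))
    nsc <- ncol(m)
    scores <- rep(10, nsc)
    nlow <- round(design$low_score_frac * nsc)
    if (nlow > 0) scores[sample(nsc, nlow)] <- sample(0:3, nlow, replace = TRUE)
    write.table(data.frame(column = seq_len(nsc), score = scores),
                file.path(outdir, "ogs", paste0(gid, ".scores.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

    # homolog tree over the same taxa (clean orthologs unless dup_rate > 0)
    ht <- simulate_homolog_tree(sub_lt, design$dup_rate, design$loss_rate,
                                seed = design$seed + 500L + i)
    if (is.null(ht)) next
    # rename the reference tip to carry the orthogroup transcript id
    ht$tree$tip.label <- sub(paste0("^", ref, "@t1$"), paste0(ref, "@", gid),
                             ht$tree$tip.label)
    names(ht$aligned_columns) <- ht$tree$tip.label
    write_newick(ht$tree, file.path(outdir, "ogs", paste0(gid, ".tree.nwk")))

    manifest$ogs[[gid]] <- list(group = grp, omega = as.list(w),
                                relax_k = design$relax_k, taxa = keep)
    ann <- rbind(ann, data.frame(transcript = paste0(ref, "@", gid),
                                 group = grp, expression = NA_real_))
  }

  # expression levels with the configured rank correlation to present-state
  # dN/dS (Gaussian copula on ranks)
  w_pres <- truth_omega[sub(".*@", "", ann$transcript), "present"]
  z_w <- qnorm((rank(w_pres) - 0.5) / length(w_pres))
  rho <- design$expr_rho
  z_e <- rho * z_w + sqrt(1 - rho^2) * rnorm(length(z_w))
  ann$expression <- round(exp(3 + 1.2 * z_e), 2)
  write.table(ann, file.path(outdir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$truth_omega <- as.data.frame(truth_omega)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
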