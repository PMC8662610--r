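#' Configuration for homolog-tree pruning and ortholog extraction
#'
#' @param abs_tip_cutoff Remove tips longer than this absolute branch length
#'   (substitutions/site; default 2).
#' @param relative_tip_factor Remove a tip longer than this factor times its
#'   sister tip's length (default 10).
#' @param internal_branch_cutoff Split trees at internal branches longer than
#'   this (default 2, mirroring the absolute tip cutoff).
#' @param min_subtree_species Minimum distinct species for a subtree produced
#'   by deep-paralog cutting to be retained (default 5).
#' @param min_og_species Minimum distinct species per final orthogroup
#'   (default 4).
#' @return A list of class `pruning_config`.
#' @export
pruning_config <- function(abs_tip_cutoff = 2, relative_tip_factor = 10,
                           internal_branch_cutoff = 2, min_subtree_species = 5L,
                           min_og_species = 4L) {
  stopifnot(abs_tip_cutoff > 0, relative_tip_factor > 0, internal_branch_cutoff > 0)
  structure(list(abs_tip_cutoff = abs_tip_cutoff,
                 relative_tip_factor = relative_tip_factor,
                 internal_branch_cutoff = internal_branch_cutoff,
                 min_subtree_species = as.integer(min_subtree_species),
                 min_og_species = as.integer(min_og_species)),
            class = "pruning_config")
}

#' Construct a homolog tree
#'
#' A homolog gene tree whose tips are labelled `species@transcript`, with
#' branch lengths in substitutions per site and, per tip, the number of
#' non-gap alignment columns of the underlying sequence (used to break ties
#' between redundant sequences of one species).
#'
#' @param tree A `phylo` with branch lengths and `species@transcript` tips.
#' @param aligned_columns Named integer vector (per tip); defaults to 0.
#' @param delim Species delimiter in tip labels (default `"@"`).
#' @return An object of class `homolog_tree`.
#' @export
homolog_tree <- function(tree, aligned_columns = NULL, delim = "@") {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("homolog tree needs at least 2 tips")
  ac <- setNames(rep(0L, length(tree$tip.label)), tree$tip.label)
  if (!is.null(aligned_columns)) {
    if (any(aligned_columns < 0)) stop("aligned_columns must be >= 0")
    ac[names(aligned_columns)] <- as.integer(aligned_columns)
  }
  structure(list(tree = tree, aligned_columns = ac, delim = delim),
            class = "homolog_tree")
}

#' @export
print.homolog_tree <- function(x, ...) {
  sp <- species_of(x$tree$tip.label, x$delim)
  cat("homolog tree:", length(sp), "tips,", length(unique(sp)), "species\n")
  invisible(x)
}

.ht_subset <- function(ht, tips) {
  if (length(tips) < 2L) return(NULL)
  homolog_tree(ape::keep.tip(ht$tree, tips), ht$aligned_columns[tips], ht$delim)
}

# length of each terminal branch, named by tip
.tip_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2] <= ntip
  setNames(tree$edge.length[term], tree$tip.label[tree$edge[term, 2]])
}

#' Remove abnormally long tips from a homolog tree
#'
#' Iterates to a fixed point: a tip is removed if its terminal branch exceeds
#' the absolute cutoff, or exceeds `relative_tip_factor` times the terminal
#' branch of its sister when that sister is itself a tip. Removing tips can
#' lengthen remaining terminal branches (unary nodes collapse), hence the
#' iteration.
#'
#' @param ht A `homolog_tree`.
#' @param cfg A [pruning_config()].
#' @return The trimmed `homolog_tree`, or `NULL` (with attribute `reason`) if
#'   fewer than 2 tips survive.
#' @export
trim_long_tips <- function(ht, cfg = pruning_config()) {
  tr <- ht$tree
  repeat {
    ntip <- length(tr$tip.label)
    tl <- .tip_lengths(tr)[tr$tip.label]
    bad <- tl > cfg$abs_tip_cutoff
    # sister-tip rule
    parent <- tr$edge[match(seq_len(ntip), tr$edge[, 2]), 1]
    for (i in seq_len(ntip)) {
      sibs <- tr$edge[tr$edge[, 1] == parent[i] & tr$edge[, 2] != i, 2]
      if (length(sibs) == 1L && sibs <= ntip) {
        if (tl[i] > cfg$relative_tip_factor * tl[sibs]) bad[i] <- TRUE
      }
    }
    if (!any(bad)) break
    keep <- tr$tip.label[!bad]
    if (length(keep) < 2L) {
      return(structure(NULL, reason = "fewer than 2 tips after trimming"))
    }
    tr <- ape::keep.tip(tr, keep)
  }
  .ht_subset(ht, tr$tip.label)
}

# per internal node: indices of descendant tips (postorder accumulation)
.node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Collapse monophyletic clusters of sequences from a single species
#'
#' Within every maximal clade whose tips all belong to one species, only the
#' sequence with the most aligned columns is retained (ties broken by the
#' lexicographically smallest transcript id).
#'
#' @param ht A `homolog_tree`.
#' @return The masked `homolog_tree`.
#' @export
mask_monophyletic_duplicates <- function(ht) {
  tr <- ht$tree
  ntip <- length(tr$tip.label)
  sp <- species_of(tr$tip.label, ht$delim)
  sets <- .node_tipsets(tr)
  nn <- ntip + tr$Nnode
  mono <- vapply(seq_len(nn), function(i) length(unique(sp[sets[[i]]])) == 1L,
                 logical(1))
  # maximal single-species nodes: monophyletic, with >1 tip, and whose parent
  # (if any) is not itself single-species
  parent <- rep(NA_integer_, nn)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  drop <- character(0)
  for (i in seq_len(nn)) {
    if (!mono[i] || length(sets[[i]]) < 2L) next
    if (!is.na(parent[i]) && mono[parent[i]]) next
    tips <- tr$tip.label[sets[[i]]]
    ac <- ht$aligned_columns[tips]
    best <- tips[order(-ac, tips)][1L]
    drop <- c(drop, setdiff(tips, best))
  }
  if (!length(drop)) return(ht)
  .ht_subset(ht, setdiff(tr$tip.label, drop))
}

#' Split a homolog tree at long internal branches
#'
#' Cuts every internal branch longer than the configured cutoff and returns
#' the resulting subtrees that contain at least `min_subtree_species` distinct
#' species. Because collapsing the cut points can merge branch lengths,
#' splitting is applied recursively until no retained subtree contains a long
#' internal branch.
#'
#' @param ht A `homolog_tree`.
#' @param cfg A [pruning_config()].
#' @return List of `homolog_tree` subtrees (possibly empty).
#' @export
cut_deep_paralogs <- function(ht, cfg = pruning_config()) {
  tr <- ht$tree
  ntip <- length(tr$tip.label)
  internal <- tr$edge[, 2] > ntip
  long <- internal & tr$edge.length > cfg$internal_branch_cutoff
  sp <- species_of(tr$tip.label, ht$delim)
  if (!any(long)) {
    ok <- length(unique(sp)) >= cfg$min_subtree_species
    return(if (ok) list(ht) else list())
  }
  # connected components of the tree graph after deleting long edges
  nn <- ntip + tr$Nnode
  comp <- seq_len(nn)
  find <- function(i) { while (comp[i] != i) i <- comp[i] <- comp[comp[i]]; i }
  for (e in seq_len(nrow(tr$edge))) {
    if (long[e]) next
    a <- find(tr$edge[e, 1]); b <- find(tr$edge[e, 2])
    if (a != b) comp[a] <- b
  }
  groups <- split(seq_len(ntip), vapply(seq_len(ntip), find, integer(1)))
  out <- list()
  for (g in groups) {
    if (length(unique(sp[g])) < cfg$min_subtree_species) next
    sub <- .ht_subset(ht, tr$tip.label[g])
    if (is.null(sub)) next
    out <- c(out, cut_deep_paralogs(sub, cfg))
  }
  out
}

# nearest-root node whose two daughters share >= 1 species, or NA
.find_duplication <- function(tree, delim) {
  ntip <- length(tree$tip.label)
  sp <- species_of(tree$tip.label, delim)
  sets <- .node_tipsets(tree)
  root <- ntip + 1L
  # breadth-first from the root
  queue <- root
  while (length(queue)) {
    nd <- queue[1L]; queue <- queue[-1L]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(kids) >= 2L) {
      spsets <- lapply(kids, function(k) unique(sp[sets[[k]]]))
      for (i in seq_along(kids)) {
        for (j in seq_along(kids)) {
          if (i < j && length(intersect(spsets[[i]], spsets[[j]]))) {
            return(list(node = nd, kids = kids,
                        sizes = vapply(spsets, length, integer(1)),
                        tipsets = lapply(kids, function(k) tree$tip.label[sets[[k]]])))
          }
        }
      }
    }
    queue <- c(queue, kids[kids > ntip])
  }
  NULL
}

#' Extract orthogroups by the rooted-ingroups (RT) algorithm
#'
#' Roots the homolog tree on the outgroup (the most distant outgroup tip when
#' several are present), discards the outgroup tips, and then repeatedly cuts
#' the smaller side off the duplication node nearest the root (a node whose
#' daughter subtrees share at least one species). Both sides are processed
#' further, so every emitted tip set contains at most one sequence per
#' species.
#'
#' @param ht A `homolog_tree`.
#' @param outgroup_species Character vector of outgroup species identifiers.
#' @param min_species Minimum distinct species per emitted orthogroup
#'   (default 1, i.e. no filtering; the pipeline filters at the union step).
#' @return List of character vectors (tip sets). If no outgroup tip is
#'   present, an empty list with attribute `reason = "unrootable"`.
#' @export
extract_orthologs_rt <- function(ht, outgroup_species, min_species = 1L) {
  tr <- ht$tree
  sp <- species_of(tr$tip.label, ht$delim)
  og_tips <- tr$tip.label[sp %in% outgroup_species]
  if (!length(og_tips)) {
    return(structure(list(), reason = "unrootable"))
  }
  # root on the outgroup tip farthest (patristic) from the ingroup
  if (length(og_tips) > 1L) {
    d <- ape::cophenetic.phylo(tr)
    far <- vapply(og_tips, function(t) {
      max(d[t, setdiff(tr$tip.label, og_tips)])
    }, numeric(1))
    root_tip <- og_tips[order(-far, og_tips)][1L]
  } else {
    root_tip <- og_tips
  }
  tr <- ape::root(tr, outgroup = root_tip, resolve.root = TRUE)
  ingroup <- setdiff(tr$tip.label, og_tips)
  if (length(ingroup) < 2L) return(list())
  out <- list()
  process <- function(tips) {
    if (length(tips) < 2L) {
      if (length(tips) == 1L) out[[length(out) + 1L]] <<- tips
      return(invisible())
    }
    sub <- ape::keep.tip(tr, tips)
    dup <- .find_duplication(sub, ht$delim)
    if (is.null(dup)) {
      out[[length(out) + 1L]] <<- sort(tips)
      return(invisible())
    }
    # cut the daughter with the fewest species (ties: fewest tips, then
    # lexicographic) and process both parts
    ord <- order(dup$sizes, vapply(dup$tipsets, length, integer(1)),
                 vapply(dup$tipsets, function(x) paste(sort(x), collapse = ","),
                        character(1)))
    smaller <- dup$tipsets[[ord[1L]]]
    process(smaller)
    process(setdiff(tips, smaller))
  }
  process(ingroup)
  sp_count <- function(x) length(unique(species_of(x, ht$delim)))
  Filter(function(x) sp_count(x) >= min_species, out)
}

#' Extract orthogroups by the maximum-inclusion (MI) algorithm
#'
#' Iteratively extracts the largest subtree (a side of some bipartition of the
#' current tree) containing at most one sequence per species, removes its
#' tips, and repeats. Ties are broken by the total number of aligned columns
#' and then by the lexicographically smallest tip-set string. Only sets with
#' at least `min_og_species` distinct species are returned.
#'
#' @param ht A `homolog_tree`.
#' @param cfg A [pruning_config()]; `cfg$min_og_species` is the size filter.
#' @return List of character vectors (tip sets), in extraction order.
#' @export
extract_orthologs_mi <- function(ht, cfg = pruning_config()) {
  out <- list()
  cur <- ht
  repeat {
    if (is.null(cur)) break
    tr <- cur$tree
    ntip <- length(tr$tip.label)
    sp <- species_of(tr$tip.label, cur$delim)
    cands <- list()
    if (!anyDuplicated(sp)) {
      cands[[1L]] <- tr$tip.label
    } else {
      sets <- .node_tipsets(tr)
      for (nd in seq_len(ntip + tr$Nnode)) {
        side1 <- tr$tip.label[sets[[nd]]]
        for (side in list(side1, setdiff(tr$tip.label, side1))) {
          if (length(side) < 2L) next
          s <- species_of(side, cur$delim)
          if (!anyDuplicated(s)) cands[[length(cands) + 1L]] <- side
        }
      }
    }
    if (!length(cands)) break
    cands <- unique(lapply(cands, sort))
    nsp <- vapply(cands, function(x) length(unique(species_of(x, cur$delim))),
                  integer(1))
    ac <- vapply(cands, function(x) sum(cur$aligned_columns[x]), numeric(1))
    key <- vapply(cands, paste, character(1), collapse = ",")
    best <- cands[[order(-lengths(cands), -ac, key)[1L]]]
    if (length(unique(species_of(best, cur$delim))) >= cfg$min_og_species) {
      out[[length(out) + 1L]] <- best
    }
    remain <- setdiff(cur$tree$tip.label, best)
    if (length(remain) < 2L) break
    cur <- .ht_subset(cur, remain)
  }
  out
}

#' Union of RT and MI orthogroups
#'
#' Keeps every RT orthogroup; MI orthogroups sharing at least one tip with any
#' RT orthogroup are discarded (the RT version is typically larger), the rest
#' pass through.
#'
#' @param rt,mi Lists of tip sets from [extract_orthologs_rt()] and
#'   [extract_orthologs_mi()].
#' @return List of tip sets.
#' @export
union_orthogroups <- function(rt, mi) {
  rt_tips <- unlist(rt)
  keep_mi <- Filter(function(x) !length(intersect(x, rt_tips)), mi)
  c(rt, keep_mi)
}

#' Full ortholog-extraction pipeline for one homolog tree
#'
#' Applies, in order: long-tip trimming, single-species duplicate masking,
#' deep-paralog cutting, RT and MI extraction per subtree, the RT-priority
#' union, and the final minimum-species filter.
#'
#' @param ht A `homolog_tree`.
#' @param outgroup_species Character vector of outgroup species.
#' @param cfg A [pruning_config()].
#' @return List of tip sets (each with at most one sequence per species and at
#'   least `cfg$min_og_species` species).
#' @export
extract_orthogroups <- function(ht, outgroup_species, cfg = pruning_config()) {
  ht <- trim_long_tips(ht, cfg)
  if (is.null(ht)) return(list())
  ht <- mask_monophyletic_duplicates(ht)
  if (is.null(ht)) return(list())
  subs <- cut_deep_paralogs(ht, cfg)
  out <- list()
  for (sub in subs) {
    rt <- extract_orthologs_rt(sub, outgroup_species)
    mi <- extract_orthologs_mi(sub, cfg)
    ogs <- union_orthogroups(rt, mi)
    sp_n <- vapply(ogs, function(x) length(unique(species_of(x, sub$delim))),
                   integer(1))
    out <- c(out, ogs[sp_n >= cfg$min_og_species])
  }
  out
}
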