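#' A tree with branch partition labels and trait-transition marks
#'
#' Wraps an [ape] `phylo` tree together with per-tip trait states (bristle
#' state: `"present"`, `"reduced"` or `"absent"`), per-branch partition labels
#' used by the branch and branch-site codon models, and optional marks
#' identifying the branches on which phylogenetically independent losses or
#' reductions of the trait occurred.
#'
#' Partition labels follow the study design: only terminal branches leading to
#' tips in a derived state are labelled (1 = reduced, 2 = absent); all internal
#' branches and branches to `"present"` tips are background (0).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_states Named character vector (`present`/`reduced`/`absent`) for
#'   every tip; missing tips default to `"present"`.
#' @param transitions Optional data.frame with columns `node` (the child node
#'   of the marked branch) and `event` (`"loss"` or `"reduction"`).
#' @return An object of class `labeled_tree`.
#' @export
labeled_tree <- function(tree, tip_states = NULL, transitions = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  states <- setNames(rep("present", length(tree$tip.label)), tree$tip.label)
  if (!is.null(tip_states)) {
    bad <- setdiff(names(tip_states), tree$tip.label)
    if (length(bad)) stop("tip_states for unknown tips: ", paste(bad, collapse = ", "))
    states[names(tip_states)] <- tip_states
  }
  if (!all(states %in% c("present", "reduced", "absent"))) {
    stop("tip states must be present/reduced/absent")
  }
  if (is.null(transitions)) {
    transitions <- data.frame(node = integer(0), event = character(0))
  }
  obj <- structure(
    list(tree = tree, tip_states = states, transitions = transitions),
    class = "labeled_tree"
  )
  obj$branch_labels <- .derive_branch_labels(obj)
  obj
}

# 0 = background/present, 1 = reduced, 2 = absent; terminal branches only
.derive_branch_labels <- function(lt) {
  tr <- lt$tree
  lab <- integer(nrow(tr$edge))
  ntip <- length(tr$tip.label)
  term <- tr$edge[, 2] <= ntip
  st <- lt$tip_states[tr$tip.label[tr$edge[term, 2]]]
  lab[term] <- c(present = 0L, reduced = 1L, absent = 2L)[st]
  lab
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("labeled tree:", length(x$tree$tip.label), "tips; states:",
      paste(names(table(x$tip_states)), table(x$tip_states), collapse = ", "),
      ";", nrow(x$transitions), "transition marks\n")
  invisible(x)
}

#' Mark a trait transition on the branch above the MRCA of a set of tips
#'
#' @param lt A `labeled_tree`.
#' @param tips Tip labels whose most recent common ancestor's parent branch
#'   carries the transition.
#' @param event `"loss"` or `"reduction"`.
#' @return The updated `labeled_tree`.
#' @export
mark_transition <- function(lt, tips, event = c("loss", "reduction")) {
  event <- match.arg(event)
  tr <- lt$tree
  bad <- setdiff(tips, tr$tip.label)
  if (length(bad)) stop("unknown tips: ", paste(bad, collapse = ", "))
  node <- if (length(tips) == 1L) {
    match(tips, tr$tip.label)
  } else {
    ape::getMRCA(tr, tips)
  }
  lt$transitions <- rbind(lt$transitions,
                          data.frame(node = node, event = event))
  lt
}

# tips descending from a node (node may itself be a tip)
.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Prune a species tree to a set of taxa
#'
#' Returns the induced subtree: unary nodes are collapsed with their branch
#' lengths summed (as in [ape::keep.tip()]), terminal partition labels are
#' re-derived from the trait map, and each transition mark is re-attached to
#' the branch above the MRCA of its surviving derived-state descendants (marks
#' with no surviving descendants are dropped).
#'
#' @param lt A `labeled_tree`.
#' @param taxa Character vector of taxa to retain (must all be present).
#' @return The pruned `labeled_tree`.
#' @export
prune_species_tree <- function(lt, taxa) {
  tr <- lt$tree
  bad <- setdiff(taxa, tr$tip.label)
  if (length(bad)) stop("taxon absent from species tree: ", paste(bad, collapse = ", "))
  # remember original descendants of each mark before pruning
  mark_desc <- lapply(lt$transitions$node, function(nd) .clade_tips(tr, nd))
  sub <- ape::keep.tip(tr, taxa)
  new_marks <- data.frame(node = integer(0), event = character(0))
  if (nrow(lt$transitions)) {
    derived <- c(loss = "absent", reduction = "reduced")
    for (i in seq_len(nrow(lt$transitions))) {
      keep <- intersect(mark_desc[[i]], taxa)
      keep <- keep[lt$tip_states[keep] == derived[[lt$transitions$event[i]]]]
      if (!length(keep)) next
      node <- if (length(keep) == 1L) match(keep, sub$tip.label) else ape::getMRCA(sub, keep)
      new_marks <- rbind(new_marks,
                         data.frame(node = node, event = lt$transitions$event[i]))
    }
  }
  labeled_tree(sub, lt$tip_states[taxa], new_marks)
}

#' Count phylogenetically independent transitions represented in a taxon set
#'
#' Counts the distinct marked loss (or reduction) branches of the species tree
#' that lie on the path from the root to at least one member of `og_taxa`
#' carrying the corresponding derived state (`absent` for losses, `reduced`
#' for reductions).
#'
#' @param og_taxa Character vector of taxa in the orthogroup.
#' @param species_lt The full species `labeled_tree` with transition marks.
#' @param event `"loss"` or `"reduction"`.
#' @return Integer count.
#' @export
count_independent_transitions <- function(og_taxa, species_lt,
                                          event = c("loss", "reduction")) {
  event <- match.arg(event)
  tr <- species_lt$tree
  bad <- setdiff(og_taxa, tr$tip.label)
  if (length(bad)) stop("taxon absent from species tree: ", paste(bad, collapse = ", "))
  derived <- c(loss = "absent", reduction = "reduced")[[event]]
  marks <- species_lt$transitions[species_lt$transitions$event == event, , drop = FALSE]
  if (!nrow(marks)) return(0L)
  n <- 0L
  for (nd in marks$node) {
    below <- intersect(.clade_tips(tr, nd), og_taxa)
    if (any(species_lt$tip_states[below] == derived)) n <- n + 1L
  }
  n
}

#' Relabel branches for a two-partition (background/foreground) contrast
#'
#' For branch-site and selection-intensity fits only two branch classes are
#' allowed. Terminal branches to tips in `foreground` state become partition 1;
#' everything else is background (0). Tips in the third state should be removed
#' before calling (the pipeline subsets each contrast to two states).
#'
#' @param lt A `labeled_tree`.
#' @param foreground `"absent"` or `"reduced"`.
#' @return The `labeled_tree` with two-partition `branch_labels`.
#' @export
label_contrast <- function(lt, foreground = c("absent", "reduced")) {
  foreground <- match.arg(foreground)
  tr <- lt$tree
  lab <- integer(nrow(tr$edge))
  ntip <- length(tr$tip.label)
  term <- tr$edge[, 2] <= ntip
  st <- lt$tip_states[tr$tip.label[tr$edge[term, 2]]]
  lab[term] <- as.integer(st == foreground)
  lt$branch_labels <- lab
  lt
}
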