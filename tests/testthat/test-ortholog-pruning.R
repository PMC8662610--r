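# helper: homolog tree from a newick string with optional aligned columns
ht_from <- function(nwk, ac = NULL) {
  homolog_tree(ape::read.tree(text = nwk), ac)
}

test_that("long tips are trimmed by the absolute and relative rules", {
  # tip of length 2.5 among short tips -> removed by the absolute 2.0 cutoff
  ht <- ht_from("((a@1:0.1,b@1:2.5):0.1,(c@1:0.1,d@1:0.1):0.1);")
  out <- trim_long_tips(ht)
  expect_setequal(out$tree$tip.label, c("a@1", "c@1", "d@1"))

  # cherry (0.05, 0.6): 0.6 > 10 x 0.05 -> relative rule removes it
  ht <- ht_from("((a@1:0.05,b@1:0.6):0.1,(c@1:0.1,d@1:0.1):0.1);")
  out <- trim_long_tips(ht)
  expect_false("b@1" %in% out$tree$tip.label)
  expect_true("a@1" %in% out$tree$tip.label)

  # post-hoc audit on random trees: no surviving tip violates either rule
  set.seed(5)
  for (rep in 1:5) {
    tr <- ape::rtree(20)
    tr$tip.label <- paste0("s", 1:20, "@t1")
    tr$edge.length <- rexp(nrow(tr$edge), 2)
    out <- trim_long_tips(homolog_tree(tr))
    if (is.null(out)) next
    tro <- out$tree
    ntip <- length(tro$tip.label)
    tl <- selcontrast:::.tip_lengths(tro)[tro$tip.label]
    expect_true(all(tl <= 2))
    for (i in seq_len(ntip)) {
      par <- tro$edge[match(i, tro$edge[, 2]), 1]
      sibs <- tro$edge[tro$edge[, 1] == par & tro$edge[, 2] != i, 2]
      if (length(sibs) == 1L && sibs <= ntip) {
        expect_lte(tl[i], 10 * tl[sibs] + 1e-12)
      }
    }
  }
})

test_that("monophyletic single-species clusters keep the best sequence", {
  ht <- ht_from("((spA@t1:0.1,spA@t2:0.1):0.1,(spB@t1:0.1,spC@t1:0.1):0.1);",
                c("spA@t1" = 300, "spA@t2" = 150, "spB@t1" = 100,
                  "spC@t1" = 100))
  out <- mask_monophyletic_duplicates(ht)
  expect_setequal(out$tree$tip.label, c("spA@t1", "spB@t1", "spC@t1"))

  # no single-species clade -> unchanged
  ht2 <- ht_from("((spA@t1:0.1,spB@t1:0.1):0.1,(spA@t2:0.1,spC@t1:0.1):0.1);")
  expect_setequal(mask_monophyletic_duplicates(ht2)$tree$tip.label,
                  ht2$tree$tip.label)

  # nested single-species clades collapse to one tip per maximal clade,
  # verified against brute-force clade enumeration
  nwk <- "(((spA@t1:0.1,spA@t2:0.1):0.1,spA@t3:0.2):0.1,(spB@t1:0.1,(spB@t2:0.05,spB@t3:0.05):0.05):0.1,spC@t1:0.3);"
  ac <- c("spA@t1" = 10, "spA@t2" = 400, "spA@t3" = 200, "spB@t1" = 50,
          "spB@t2" = 50, "spB@t3" = 50, "spC@t1" = 100)
  out <- mask_monophyletic_duplicates(ht_from(nwk, ac))
  # spA clade (all three tips monophyletic): keep max columns = spA@t2
  # spB clade: tie at 50 -> lexicographically smallest = spB@t1
  expect_setequal(out$tree$tip.label, c("spA@t2", "spB@t1", "spC@t1"))
  # brute force: every remaining clade is multi-species or a single tip
  sets <- selcontrast:::.node_tipsets(out$tree)
  sp <- species_of(out$tree$tip.label)
  for (s in sets) {
    if (length(s) >= 2L && all(s <= length(sp))) {
      expect_gt(length(unique(sp[s])), 1L)
    }
  }
})

test_that("deep paralogs are split at long internal branches", {
  # one long internal branch separating 6 + 6 species -> two subtrees
  left <- paste0("(", paste0("l", 1:6, "@t1:0.1", collapse = ","), ")")
  right <- paste0("(", paste0("r", 1:6, "@t1:0.1", collapse = ","), ")")
  nwk <- paste0("(", left, ":3.0,", right, ":0.1);")
  subs <- cut_deep_paralogs(ht_from(nwk))
  expect_length(subs, 2L)
  sizes <- sort(vapply(subs, function(h) length(h$tree$tip.label), integer(1)))
  expect_equal(sizes, c(6L, 6L))
  for (h in subs) {
    internal <- h$tree$edge[, 2] > length(h$tree$tip.label)
    expect_true(all(h$tree$edge.length[internal] <= 2))
  }

  # a split yielding 6 and 3 species keeps only the 6-species part
  small <- paste0("(", paste0("r", 1:3, "@t1:0.1", collapse = ","), ")")
  nwk2 <- paste0("(", left, ":3.0,", small, ":0.1);")
  subs2 <- cut_deep_paralogs(ht_from(nwk2))
  expect_length(subs2, 1L)
  expect_equal(length(subs2[[1]]$tree$tip.label), 6L)

  # no long branch -> identity
  expect_length(cut_deep_paralogs(ht_from(
    paste0("(", left, ":0.3,", right, ":0.1);"))), 1L)
})

test_that("rooted-ingroup extraction splits at duplication nodes", {
  # no duplications -> one orthogroup with all ingroup tips
  nwk <- "(((A@1:0.1,B@1:0.1):0.1,C@1:0.1):0.1,out@1:0.5);"
  ogs <- extract_orthologs_rt(ht_from(nwk), "out")
  expect_length(ogs, 1L)
  expect_setequal(ogs[[1]], c("A@1", "B@1", "C@1"))

  # duplication at the ingroup root (A on both sides) -> two candidates
  nwk2 <- "(((A@1:0.1,B@1:0.1):0.1,(A@2:0.1,C@1:0.1):0.1):0.1,out@1:0.5);"
  ogs2 <- extract_orthologs_rt(ht_from(nwk2), "out")
  expect_length(ogs2, 2L)
  expect_setequal(lapply(ogs2, sort),
                  list(c("A@1", "B@1"), c("A@2", "C@1")))

  # no outgroup tip -> flagged unrootable
  no_out <- extract_orthologs_rt(ht_from("((A@1:0.1,B@1:0.1):0.1,C@1:0.1);"),
                                 "out")
  expect_length(no_out, 0L)
  expect_equal(attr(no_out, "reason"), "unrootable")

  # property: no emitted set ever contains two tips of one species
  species_lt <- fixture_labeled_tree(10, absent = "sp2", reduced = "sp3",
                                     seed = 2)
  for (i in 1:25) {
    ht <- simulate_homolog_tree(species_lt, dup_rate = 0.5, loss_rate = 0.2,
                                seed = 100 + i)
    if (is.null(ht)) next
    # attach an artificial outgroup to root on
    tr <- ht$tree
    out_nwk <- paste0("(", sub(";$", "", ape::write.tree(tr)),
                      ":0.2,out@1:0.5);")
    ht2 <- homolog_tree(ape::read.tree(text = out_nwk), ht$aligned_columns)
    for (og in extract_orthologs_rt(ht2, "out")) {
      expect_false(anyDuplicated(species_of(og)) > 0)
    }
  }
})

test_that("maximum-inclusion extraction matches exhaustive split search", {
  # duplication-free tree -> single orthogroup containing every tip
  nwk <- "((A@1:0.1,B@1:0.1):0.1,(C@1:0.1,D@1:0.1):0.1);"
  ogs <- extract_orthologs_mi(ht_from(nwk), pruning_config(min_og_species = 2))
  expect_length(ogs, 1L)
  expect_length(ogs[[1]], 4L)

  # 10-tip fixture with two duplicated species: compare against exhaustive
  # search over all bipartition sides with <= 1 sequence per species
  set.seed(9)
  nwk2 <- "(((A@1:0.1,B@1:0.1):0.05,(C@1:0.1,(A@2:0.1,D@1:0.1):0.05):0.05):0.05,((E@1:0.1,(B@2:0.1,F@1:0.1):0.05):0.05,(G@1:0.1,H@1:0.1):0.05):0.05);"
  ac <- setNames(seq(110, 200, by = 10),
                 c("A@1", "B@1", "C@1", "A@2", "D@1", "E@1", "B@2", "F@1",
                   "G@1", "H@1"))
  ht <- ht_from(nwk2, ac)
  cfg <- pruning_config(min_og_species = 2)
  got <- extract_orthologs_mi(ht, cfg)

  exhaustive_best <- function(h) {
    tr <- h$tree
    sets <- selcontrast:::.node_tipsets(tr)
    cands <- list(tr$tip.label)
    for (nd in seq_along(sets)) {
      side <- tr$tip.label[sets[[nd]]]
      for (s in list(side, setdiff(tr$tip.label, side))) {
        if (length(s) >= 2L && !anyDuplicated(species_of(s))) {
          cands[[length(cands) + 1L]] <- sort(s)
        }
      }
    }
    cands <- unique(Filter(function(s) !anyDuplicated(species_of(s)), cands))
    ac_tot <- vapply(cands, function(s) sum(h$aligned_columns[s]), numeric(1))
    key <- vapply(cands, paste, character(1), collapse = ",")
    cands[[order(-lengths(cands), -ac_tot, key)[1L]]]
  }
  expect_setequal(got[[1]], exhaustive_best(ht))

  # extracted orthogroups are disjoint and cover at most all tips
  expect_false(anyDuplicated(unlist(got)) > 0)
  expect_true(all(unlist(got) %in% ht$tree$tip.label))
})

test_that("the RT-priority union keeps RT orthogroups on overlap", {
  rt <- list(c("A@1", "B@1", "C@1"))
  mi <- list(c("A@1", "B@1"), c("D@1", "E@1"))
  got <- union_orthogroups(rt, mi)
  expect_length(got, 2L)
  expect_true(any(vapply(got, identical, logical(1), c("A@1", "B@1", "C@1"))))
  expect_true(any(vapply(got, identical, logical(1), c("D@1", "E@1"))))

  expect_equal(union_orthogroups(list(), mi), mi)

  # property: every output is an RT set or an MI set disjoint from all RT
  set.seed(3)
  for (i in 1:20) {
    rt <- lapply(1:3, function(j) paste0("s", sample(20, sample(2:5, 1)), "@1"))
    mi <- lapply(1:3, function(j) paste0("s", sample(20, sample(2:5, 1)), "@1"))
    got <- union_orthogroups(rt, mi)
    for (og in got) {
      in_rt <- any(vapply(rt, identical, logical(1), og))
      if (!in_rt) {
        expect_true(any(vapply(mi, identical, logical(1), og)))
        expect_length(intersect(og, unlist(rt)), 0L)
      }
    }
  }
})

test_that("the full extraction pipeline is idempotent and has perfect recall
           on duplication-free homolog trees", {
  species_lt <- fixture_labeled_tree(10, absent = "sp2", reduced = "sp3",
                                     seed = 4)
  cfg <- pruning_config()
  for (i in 1:10) {
    ht <- simulate_homolog_tree(species_lt, dup_rate = 0, loss_rate = 0,
                                seed = i)
    ogs <- extract_orthogroups(ht, "out", cfg)
    # no outgroup in these trees: MI alone must recover the single orthogroup
    expect_length(ogs, 1L)
    expect_setequal(ogs[[1]], ht$tree$tip.label)
  }

  # idempotence: rerunning on an extracted orthogroup subtree changes nothing
  ht <- simulate_homolog_tree(species_lt, dup_rate = 0.3, loss_rate = 0.1,
                              seed = 77)
  ogs <- extract_orthogroups(ht, "out", cfg)
  for (og in ogs) {
    sub <- homolog_tree(ape::keep.tip(ht$tree, og), ht$aligned_columns[og])
    again <- extract_orthogroups(sub, "out", cfg)
    expect_length(again, 1L)
    expect_setequal(again[[1]], og)
  }
  # every final orthogroup: <= 1 sequence per species, >= 4 species
  for (og in ogs) {
    expect_false(anyDuplicated(species_of(og)) > 0)
    expect_gte(length(unique(species_of(og))), 4L)
  }
})
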