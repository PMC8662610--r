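#' Load a study directory produced by [generate_study()] (or hand-assembled)
#'
#' @param study_dir Directory containing `species_tree.nwk`, `traits.tsv`,
#'   `transitions.tsv`, `annotation.tsv` and an `ogs/` subdirectory with
#'   per-orthogroup `<id>.aa.fasta`, `<id>.cds.fasta`, `<id>.scores.tsv`,
#'   `<id>.tree.nwk`.
#' @return A list with `species_lt`, `annotation` and `og_ids`.
#' @export
load_study <- function(study_dir) {
  tr <- read_newick(file.path(study_dir, "species_tree.nwk"))
  traits <- read.table(file.path(study_dir, "traits.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  lt <- labeled_tree(tr, setNames(traits$state, traits$species))
  tf <- file.path(study_dir, "transitions.tsv")
  if (file.exists(tf)) {
    trans <- read.table(tf, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    for (i in seq_len(nrow(trans))) {
      lt <- mark_transition(lt, strsplit(trans$tips[i], ",")[[1]],
                            trans$event[i])
    }
  }
  ann <- read_annotation_table(file.path(study_dir, "annotation.tsv"))
  ids <- sort(sub("\\.aa\\.fasta$", "",
                  basename(Sys.glob(file.path(study_dir, "ogs", "*.aa.fasta")))))
  list(species_lt = lt, annotation = ann, og_ids = ids, dir = study_dir)
}

# run every fit for one orthogroup; returns a list of result fragments
.analyze_og <- function(gid, study, models, contrasts, lrt_df_branch_site) {
  sdir <- study$dir
  aa <- read_fasta(file.path(sdir, "ogs", paste0(gid, ".aa.fasta")))
  cds <- read_fasta(file.path(sdir, "ogs", paste0(gid, ".cds.fasta")))
  scores <- read_column_scores(file.path(sdir, "ogs", paste0(gid, ".scores.tsv")))
  gt <- read_newick(file.path(sdir, "ogs", paste0(gid, ".tree.nwk")))
  ac <- setNames(nchar(gsub("-", "", aa)), names(aa))
  ht <- homolog_tree(gt, ac[gt$tip.label])

  outgroup <- unique(grep("^out", species_of(gt$tip.label), value = TRUE))
  ogs <- extract_orthogroups(ht, outgroup)
  if (!length(ogs)) return(list(status = "excluded", reason = "no_orthogroup"))
  ann_row <- study$annotation[study$annotation$transcript %in% unlist(ogs), ,
                              drop = FALSE]
  has_ref <- vapply(ogs, function(x) any(x %in% study$annotation$transcript),
                    logical(1))
  pick <- if (any(has_ref)) which(has_ref)[1L] else which.max(lengths(ogs))
  tips <- setdiff(ogs[[pick]], grep("^out", ogs[[pick]], value = TRUE))
  tips <- intersect(tips, names(aa))
  if (length(tips) < 4L) return(list(status = "excluded", reason = "min_4_species"))

  grp <- if (nrow(ann_row)) ann_row$group[1L] else NA_character_
  expr <- if (nrow(ann_row) && "expression" %in% names(ann_row)) {
    ann_row$expression[1L]
  } else NA_real_
  prep <- prepare_orthogroup(gid, aa[tips], cds[tips], scores,
                             study$species_lt, grp)
  if (!prep$ok) return(list(status = "excluded", reason = prep$rule))
  og <- prep$og

  m0 <- fit_single_omega(og)
  states <- og$tree$tip_states[rownames(og$alignment)]
  out <- list(status = "analyzed", og = og, expr = expr,
              branch = data.frame(
                og_id = gid, group = grp, n_taxa = nrow(og$alignment),
                n_codons = ncol(og$alignment),
                n_losses = og$n_independent_losses,
                n_reductions = og$n_independent_reductions,
                kappa = m0$params$kappa, omega_m0 = m0$params$omega,
                lnl_m0 = m0$lnL,
                omega_present = NA_real_, omega_reduced = NA_real_,
                omega_absent = NA_real_, lrt_p = NA_real_,
                pattern_coarse = NA_character_, pattern_fine = NA_character_,
                stringsAsFactors = FALSE))

  if ("branch3" %in% models && all(c("present", "reduced", "absent") %in% states)) {
    b3 <- fit_branch_three_omega(og, m0 = m0)
    if (inherits(b3, "fit_result")) {
      tst <- lrt(m0, b3, df = 2)
      pat <- classify_omega_pattern(b3$params$omega[["present"]],
                                    b3$params$omega[["reduced"]],
                                    b3$params$omega[["absent"]])
      out$branch$omega_present <- b3$params$omega[["present"]]
      out$branch$omega_reduced <- b3$params$omega[["reduced"]]
      out$branch$omega_absent <- b3$params$omega[["absent"]]
      out$branch$lrt_p <- tst$p
      out$branch$pattern_coarse <- pat$coarse
      out$branch$pattern_fine <- pat$fine
    }
  }

  for (fg in contrasts) {
    keep <- names(states)[states %in% c("present", fg)]
    if (length(keep) < 4L || !any(states[keep] == fg) ||
        !any(states[keep] == "present")) next
    sub_aln <- codon_alignment(unclass(og$alignment)[keep, , drop = FALSE])
    sub_og <- orthogroup(gid, sub_aln, prune_species_tree(study$species_lt, keep),
                         grp, study$species_lt)
    m0s <- fit_single_omega(sub_og)

    if ("modelA" %in% models) {
      a0 <- fit_model_a_null(sub_og, fg, m0 = m0s)
      a1 <- fit_model_a(sub_og, fg, m0 = m0s, init = a0)
      if (inherits(a0, "fit_result") && inherits(a1, "fit_result")) {
        t2 <- lrt(a0, a1, df = lrt_df_branch_site)
        t1 <- lrt(a0, a1, df = 1)
        out$branch_site <- rbind(out$branch_site, data.frame(
          og_id = gid, group = grp, contrast = fg,
          n_taxa = nrow(sub_aln),
          n_transitions = if (fg == "absent") sub_og$n_independent_losses
                          else sub_og$n_independent_reductions,
          w2 = a1$params$w2, lnl_null = a0$lnL, lnl_alt = a1$lnL,
          statistic = t2$statistic, p = t2$p, p_df1 = t1$p,
          stringsAsFactors = FALSE))
      }
    }
    if ("relax" %in% models) {
      r0 <- fit_relax(sub_og, fg, fix_k = 1, m0 = m0s)
      r1 <- fit_relax(sub_og, fg, m0 = m0s, init = r0)
      if (inherits(r0, "fit_result") && inherits(r1, "fit_result")) {
        tt <- lrt(r0, r1, df = 1)
        out$relax <- rbind(out$relax, data.frame(
          og_id = gid, group = grp, contrast = fg, k = r1$params$k,
          lnl_null = r0$lnL, lnl_alt = r1$lnL,
          statistic = tt$statistic, p = tt$p,
          k_at_bound = "k_at_bound" %in% r1$flags,
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# chi-square contrast table for one subset of significant rows
.contrast_table <- function(sig_groups, all_groups, group_levels) {
  O <- table(factor(sig_groups, levels = group_levels))
  T <- table(factor(all_groups, levels = group_levels))
  keep <- T > 0
  tab <- data.frame(group = group_levels[keep],
                    significant = as.integer(O[keep]),
                    pct = round(100 * as.integer(O[keep]) / as.integer(T[keep]), 1),
                    total = as.integer(T[keep]))
  test <- if (sum(O) > 0 && sum(keep) >= 2) {
    chi_square_expected(as.integer(O[keep]), as.integer(T[keep]))
  } else NULL
  list(table = tab, test = test)
}

#' Run the full comparative analysis on a study directory
#'
#' Orchestrates ortholog extraction, alignment preparation, model fitting
#' (single-omega, three-state branch model, branch-site model A and the
#' selection-intensity model, over the present-absent and present-reduced
#' contrasts) and the statistical contrast layer, mirroring the published
#' analysis design. Deterministic given the study directory and `seed`.
#'
#' @param study_dir Study directory (see [load_study()]).
#' @param out_dir Optional output directory for summary TSV/JSON files.
#' @param models Character subset of `c("m0", "branch3", "modelA", "relax")`.
#' @param contrasts Foreground states to contrast against `present`.
#' @param alpha Significance threshold on the uncorrected LRT p-value used to
#'   build contrast tables (default 0.05, with q-values reported alongside).
#' @param lrt_df_branch_site Degrees of freedom for the branch-site LRT
#'   (default 2, following the published analysis; the 1-df p-value is also
#'   reported).
#' @param min_transitions Minimum independent losses for the stratified
#'   re-analysis (default 3).
#' @param seed Seed controlling optimizer restarts (default 1).
#' @return A list with data.frames `branch`, `branch_site`, `relax`, the run
#'   `log`, and `stats` (group and state contrasts, chi-square tables,
#'   codon-usage bias, expression correlation, stratified results).
#' @export
run_study <- function(study_dir, out_dir = NULL,
                      models = c("m0", "branch3", "modelA", "relax"),
                      contrasts = c("absent", "reduced"), alpha = 0.05,
                      lrt_df_branch_site = 2, min_transitions = 3L,
                      seed = 1L) {
  set.seed(seed)
  study <- load_study(study_dir)
  branch <- branch_site <- relax_df <- NULL
  run_log <- data.frame(og_id = character(0), status = character(0),
                        reason = character(0))
  ogs <- list(); exprs <- numeric(0)
  for (gid in study$og_ids) {
    res <- tryCatch(
      .analyze_og(gid, study, models, contrasts, lrt_df_branch_site),
      error = function(e) list(status = "excluded", reason = conditionMessage(e)))
    run_log <- rbind(run_log, data.frame(
      og_id = gid, status = res$status,
      reason = if (res$status == "analyzed") "" else res$reason))
    if (res$status != "analyzed") next
    branch <- rbind(branch, res$branch)
    if (!is.null(res$branch_site)) branch_site <- rbind(branch_site, res$branch_site)
    if (!is.null(res$relax)) relax_df <- rbind(relax_df, res$relax)
    ogs[[gid]] <- res$og
    exprs[gid] <- res$expr
  }
  if (is.null(branch) || nrow(branch) == 0L) {
    stop("no orthogroup passed the pipeline")
  }

  # q-values per model family
  if (any(!is.na(branch$lrt_p))) {
    ok <- !is.na(branch$lrt_p)
    branch$lrt_q <- NA_real_
    branch$lrt_q[ok] <- qvalues(branch$lrt_p[ok])$qvalues
  }
  for (nm in c("branch_site", "relax_df")) {
    df <- get(nm)
    if (!is.null(df) && nrow(df)) {
      df$q <- qvalues(df$p)$qvalues
      assign(nm, df)
    }
  }

  group_levels <- unique(study$annotation$group)
  stats <- list()

  # Kruskal-Wallis + post-hoc across annotation groups on single-omega values
  gb <- split(branch$omega_m0, factor(branch$group, levels = group_levels))
  gb <- gb[lengths(gb) >= 2L]
  if (length(gb) >= 2L) {
    stats$kw_groups <- kruskal_wallis(gb)
    if (length(gb) >= 3L) stats$dscf_groups <- dscf_posthoc(gb)
  }

  # contrasts across bristle states within/aggregated over groups, using OGs
  # better explained by the three-state model
  b3 <- branch[!is.na(branch$lrt_p) & branch$lrt_p < alpha, , drop = FALSE]
  if (nrow(b3) >= 3L) {
    stats$kw_states_pooled <- kruskal_wallis(list(
      present = b3$omega_present, reduced = b3$omega_reduced,
      absent = b3$omega_absent))
    stats$pattern_counts <- table(b3$pattern_coarse)
    stats$pattern_fine_counts <- table(b3$pattern_fine)
    sig_plus <- b3$group[b3$pattern_coarse == "+"]
    ct <- .contrast_table(sig_plus, branch$group[!is.na(branch$lrt_p)],
                          group_levels)
    stats$chisq_pattern_plus <- ct$test
  }

  # chi-square tables for branch-site and selection-intensity contrasts
  if (!is.null(branch_site) && nrow(branch_site)) {
    stats$branch_site_tables <- lapply(split(branch_site, branch_site$contrast),
      function(df) .contrast_table(df$group[df$p < alpha], df$group, group_levels))
  }
  if (!is.null(relax_df) && nrow(relax_df)) {
    stats$relax_tables <- lapply(split(relax_df, relax_df$contrast), function(df) {
      sig <- df[df$p < alpha, , drop = FALSE]
      list(all = .contrast_table(sig$group, df$group, group_levels),
           intensified = .contrast_table(sig$group[sig$k > 1], df$group, group_levels),
           relaxed = .contrast_table(sig$group[sig$k < 1], df$group, group_levels),
           frac_relaxed = nrow(sig[sig$k < 1, ]) / nrow(df),
           frac_intensified = nrow(sig[sig$k > 1, ]) / nrow(df))
    })
  }

  # codon-usage bias of absent-state sequences against present-state reference
  bias <- vapply(ogs, function(og) {
    st <- og$tree$tip_states[rownames(og$alignment)]
    if (!any(st == "absent") || !any(st == "present")) return(NA_real_)
    m <- unclass(og$alignment)
    cnt <- function(rows) {
      cd <- m[rows, , drop = FALSE]
      table(cd[.is_plain_codon(cd)])
    }
    g <- cnt(which(st == "absent")); r <- cnt(which(st == "present"))
    tryCatch(codon_usage_bias_b(g, r), error = function(e) NA_real_)
  }, numeric(1))
  stats$mean_codon_usage_bias <- mean(bias, na.rm = TRUE)

  # expression level versus single-omega estimate
  ex <- exprs[branch$og_id]
  ok <- !is.na(ex)
  if (sum(ok) >= 5L) stats$spearman_expr <- spearman(ex[ok], branch$omega_m0[ok])

  # stratified re-analysis: orthogroups covering >= min_transitions losses
  strat <- stratify_by_transitions(branch, min_transitions, "n_losses")
  if (nrow(strat) >= 3L) {
    gs <- split(strat$omega_m0, factor(strat$group, levels = group_levels))
    gs <- gs[lengths(gs) >= 2L]
    if (length(gs) >= 2L) stats$kw_groups_stratified <- kruskal_wallis(gs)
  }

  results <- list(branch = branch, branch_site = branch_site,
                  relax = relax_df, stats = stats, log = run_log)
  if (!is.null(out_dir)) .write_study_outputs(results, out_dir)
  results
}

.write_study_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible())
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    # reported omegas are capped to [0.01, 10] in summary tables only
    for (cn in grep("^omega", names(df), value = TRUE)) df[[cn]] <- cap_omega(df[[cn]])
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(results$branch, "branch_models.tsv")
  wr(results$branch_site, "branch_site_models.tsv")
  wr(results$relax, "relax_models.tsv")
  wr(results$log, "run_log.tsv")
  stats <- results$stats
  jsonlite::write_json(
    rapply(stats, function(x) if (is.table(x)) as.list(x) else x, how = "replace"),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = 8,
    force = TRUE)
  invisible(out_dir)
}

#' Filter results to orthogroups covering enough independent transitions
#'
#' @param results A data.frame with a transition-count column.
#' @param min_transitions Minimum count to retain a row (default 3; 0 returns
#'   the input unchanged).
#' @param column Name of the count column (default `"n_losses"`).
#' @return The filtered data.frame (warns if empty).
#' @export
stratify_by_transitions <- function(results, min_transitions = 3L,
                                    column = "n_losses") {
  stopifnot(column %in% names(results))
  out <- results[!is.na(results[[column]]) &
                   results[[column]] >= min_transitions, , drop = FALSE]
  if (!nrow(out)) warning("no orthogroup passes the transition filter")
  out
}
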