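#' Reference significant-orthogroup counts from the genus-wide bristle-state
#' contrast study
#'
#' Observed counts of significant orthogroups and totals tested per
#' annotation group, for the branch-site (positive-selection) and
#' selection-intensity contrasts of a genus-wide comparison of flatworm
#' lineages with present, reduced or absent sperm bristles. Shipped as
#' package data so that the chi-square goodness-of-fit layer can be exercised
#' and checked against the published summary statistics without any external
#' download.
#'
#' @param which `"branch_site"` or `"relax"`.
#' @return A data.frame with columns `group`, `contrast`,
#'   (`direction` for the selection-intensity table), `significant`, `total`.
#' @export
reference_contrast_counts <- function(which = c("branch_site", "relax")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_contrast_counts.tsv"),
                   package = "selcontrast")
  read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Chi-square test of a reference contrast table slice
#'
#' Convenience wrapper: selects one contrast (and direction, for the
#' selection-intensity table) from [reference_contrast_counts()] and runs
#' [chi_square_expected()] on it.
#'
#' @param which `"branch_site"` or `"relax"`.
#' @param contrast `"present_absent"` or `"present_reduced"`.
#' @param direction For `which = "relax"`: `"all"`, `"k_gt1"` or `"k_lt1"`.
#' @return A `test_result` (see [chi_square_expected()]).
#' @export
reference_contrast_test <- function(which = c("branch_site", "relax"),
                                    contrast = c("present_absent",
                                                 "present_reduced"),
                                    direction = "all") {
  which <- match.arg(which)
  contrast <- match.arg(contrast)
  tab <- reference_contrast_counts(which)
  tab <- tab[tab$contrast == contrast, , drop = FALSE]
  if (which == "relax") tab <- tab[tab$direction == direction, , drop = FALSE]
  chi_square_expected(setNames(tab$significant, tab$group), tab$total)
}
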