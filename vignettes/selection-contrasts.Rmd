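---
title: "Codon-model contrasts of selection across lineages with divergent sperm morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model contrasts of selection across lineages with divergent sperm morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Free-living flatworms of the genus *Macrostomum* are simultaneous
hermaphrodites whose mating strategies fall into two broad syndromes:
reciprocal copulation, associated with sperm bearing stiff lateral bristles,
and hypodermic insemination, associated with simplified, bristle-less sperm.
Bristles have been lost (and in some lineages reduced) many times
independently, so the genus offers a replicated natural experiment: do
reproduction-related genes evolve faster than ubiquitously expressed genes,
and do lineages with the derived sperm morphology show different selective
regimes genome-wide?

`selcontrast` implements the full comparative pipeline for this kind of
question: tree-based ortholog extraction from homolog gene trees, codon
alignment preparation, maximum-likelihood codon substitution models (branch,
branch-site, and selection-intensity families), and the statistical contrast
layer that turns per-orthogroup fits into group-level conclusions. A
synthetic-data module generates every input the pipeline consumes, so all
stages are testable end-to-end without any external download.

## Models

All substitution models are Goldman–Yang style Markov processes on the 61
sense codons of the standard genetic code. Off-diagonal rates are zero unless
the two codons differ at one nucleotide position, and otherwise

\[ q_{ij} = \pi_j \, \kappa^{\mathbb{1}[\text{transition}]} \,
            \omega^{\mathbb{1}[\text{nonsynonymous}]} , \]

with \(\pi\) the equilibrium codon frequencies (F3x4 by default, estimated
per orthogroup with a 0.5 pseudo-count per nucleotide per position),
\(\kappa\) the transition/transversion rate ratio, and \(\omega =
d_N/d_S\). A single generator is scaled to one expected substitution per
codon at equilibrium, so branch lengths are in expected substitutions per
codon.

**Mixture scaling.** For models with several \(\omega\) classes, all class
matrices share one common scale: a class with ratio \(\omega\) evolves at
relative rate \((a + b\,\omega)/f\), where \(a\) and \(b\) are the
synonymous and nonsynonymous equilibrium fluxes at the fitted \(\kappa\) and
\(f\) is the proportion-weighted mean rate over classes on
background/reference branches. This is the convention of the standard tools
in this field; scaling every class to unit rate individually would make
\(\omega\) affect only the *composition* of change, not its *amount*, and
would largely erase the signature of episodic positive selection. The
simulator uses the identical convention, so simulation–inference checks are
exact.

The implemented model families:

* **M0 (single ratio)** — one \(\omega\) for all branches and sites. Fitted
  with free \(\kappa\), \(\omega\) (initial values 2 and 0.001) and a global
  branch-length scale converting the input tree (substitutions/site) to
  codon units. The fitted scale is then held fixed for all richer models of
  the same orthogroup; this stabilises the mixture fits and mirrors common
  practice of estimating branch lengths under a simple model.
* **Three-state branch model** — separate \(\omega\) for terminal branches
  leading to bristle-present, -reduced and -absent species (internal
  branches are background). Compared against M0 by an LRT with 2 df.
* **Branch-site model A** — four site classes 0, 1, 2a, 2b with proportions
  \(p_0, p_1, p_{2a}, p_{2b}\); classes 2a/2b allow \(\omega_2 \ge 1\) on
  the foreground partition only. The null fixes \(\omega_2 = 1\). The LRT
  uses 2 df by default, following the published analysis convention, and the
  1-df p-value is reported alongside (the conventional choice; both are in
  the output so the reader can pick). Sites are flagged by naive empirical
  Bayes at the MLEs when the posterior mass of classes 2a+2b exceeds 0.95 —
  there is no integration over parameter uncertainty (no BEB).
* **Selection-intensity (RELAX-style)** — three \(\omega\) categories with
  \(\omega_0 \le \omega_1 \le 1 \le \omega_2\) on reference branches and
  \(\omega_i^k\) on test branches; \(k < 1\) is relaxation, \(k > 1\)
  intensification, \(k = 1\) the null (LRT, 1 df). Following the branch-site
  random-effects framework in which this method is defined, the category is
  drawn independently for every branch and site, i.e. each branch's
  transition kernel is the proportion-weighted mixture of its partition's
  category matrices. The partitioned descriptive model (PDM) frees the
  category values and proportions per partition in the same framework, which
  is what makes the nesting \(\ln L_{\mathrm{PDM}} \ge
  \ln L_{\mathrm{alt}} \ge \ln L_{\mathrm{null}}\) hold; a PDM with site
  categories shared across branches but independent proportions would not
  nest the \(k\)-model, which is why the shared-category formulation is not
  used here. (Branch-site model A, in contrast, is genuinely a shared-class
  model and is implemented as such.)

Likelihoods are computed by Felsenstein pruning over compressed site
patterns with per-node scaling, using the spectral decomposition of the
reversible generator (\(P(t) = U e^{\Lambda t} U^{-1}\)); the per-pattern
kernel is in compiled code. Optimisation is bounded quasi-Newton (`nlminb`)
on transformed parameters — log for \(\kappa\), \(\omega\), \(k\) and the
scale, logit/additive-logistic for proportions, \(\log(\omega_2 - 1)\) for
the positive-selection ratio — with up to two random restarts on
non-convergence. Warm starts chain the fits (null → alternative → PDM),
which both saves time and guarantees the nesting inequalities at the
optimum; the \(\omega_2\) start is floored at 1.5 because the
\(\log(\omega_2-1)\) transform has a vanishing gradient at the null
boundary.

## Ortholog extraction and alignment preparation

Homolog trees (tips `species@transcript`) are reduced to one-per-species
orthogroups in the published order:

1. **Long-tip trimming** — remove tips longer than 2 substitutions/site or
   more than 10× their sister tip, iterated to a fixed point (removal can
   lengthen remaining tips by collapsing unary nodes).
2. **Duplicate masking** — in every maximal clade of one species keep the
   sequence with most aligned columns (ties: lexicographically smallest id).
3. **Deep-paralog cutting** — split at internal branches longer than the
   cutoff (default 2.0, mirroring the tip cutoff; the original description
   gives no number, so it is configuration-exposed) and keep subtrees with
   at least 5 species, reapplied recursively because collapsed cut points
   can merge branch lengths.
4. **RT and MI extraction** — "rooted ingroups": root on the most distant
   outgroup tip, then repeatedly cut the smaller side off the duplication
   node nearest the root; "maximum inclusion": iteratively take the largest
   bipartition side with at most one sequence per species (ties by total
   aligned columns, then lexicographic). The union keeps the RT orthogroup
   wherever the two overlap.

Alignment preparation is strictly ordered — back-translation, removal of
codon columns whose amino-acid reliability score is ≤ 3 (scores are consumed
as input on a nominal 1–10 scale; computing them is out of scope), removal
of sequences whose gap-less length falls below 50% of the alignment,
validation (no stop codons, ≥ 80 nt, ≥ 4 species), species-tree pruning —
because permuting the trimming and dropping steps can change the result.
Codons containing gaps or ambiguity codes are treated as fully missing in
the likelihood (the least-biased treatment; the likelihood then sums over
all 61 states). Orthogroups whose reference-species sequence is lost to
filtering keep their annotation.

## The statistics layer

Per model family, LRT p-values are converted to Storey q-values: \(\pi_0\)
is estimated on the grid \(\lambda = 0.05, \dots, 0.95\) with the spline
smoother (bootstrap available; the published analysis does not state which
variant was used), and \(q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)}/j \le
\pi_0\). Contrast tables of significant orthogroups per annotation group are
tested against the expectation proportional to all orthogroups tested per
group (\(\chi^2\), df = groups − 1). Group and state comparisons use
Kruskal–Wallis tests with Dwass–Steele–Critchlow–Fligner all-pairs post-hoc
tests (large-sample studentized-range reference; no exact small-sample
tables). Contrast tables are built from uncorrected LRT p < 0.05 — matching
the published choice to retain all nominally significant orthogroups for
stratified exploration — with q-values reported alongside. Further
diagnostics: the \(\omega\) pattern across bristle states (coarse −/+ and
fine −/−, −/+, +/−, +/+; exact ties classify "+" with a flag),
phylogenetically independent transition counts (marked species-tree branches
on the root path of at least one derived-state member), Nei–Gojobori mean
pairwise dS with Jukes–Cantor correction (pairs with synonymous difference
proportion ≥ 0.75 reported as saturated and excluded), Karlin–Mrázek
codon-usage bias B of derived-state sequences against the present-state
reference, and the Spearman correlation between expression level and
\(\omega\). Reported \(\omega\) values in summary tables are capped to
\([0.01, 10]\); stored MLEs never are.

## The synthetic-data generator

`study_design()` fixes the study conditions: 16 ingroup species and 2
outgroups on a pure-birth tree of height 1; 3 independent losses and 2
reductions on non-nested branches (small clades preferred so the ancestral
state stays in the majority); 80 orthogroups split 40/10/10/20 across
testis-region, ovary-region, tail-region and ubiquitous annotations; 300
codons per alignment. Per-orthogroup \(\omega\) values are lognormal
(sdlog 0.4) around group means 0.20/0.18/0.18/0.10 multiplied by state
factors 1/1.4/1.8 (present/reduced/absent) — encoding the two orderings the
analysis is designed to detect, reproduction-related > ubiquitous and
derived states > present, at effect sizes a comparative transcriptomic study
of this scale could plausibly show. Expression levels are lognormal with a
configurable Spearman correlation to \(\omega\) (default −0.6, negative
because highly expressed genes evolve slowly). Alignments carry 3% random
gaps and 10% low-reliability columns to exercise the filters. Homolog trees
evolve inside the species tree with Poisson duplications and losses; the
true ortholog partition (by locus) and per-site class assignments are
recorded as ground truth.

What the generator does *not* emulate: assembly fragmentation and chimeras,
alignment error, codon-usage heterogeneity between lineages, rate variation
beyond the modelled classes, or gene-tree discordance from incomplete
lineage sorting. Passing recovery tests therefore demonstrates correctness
of the inference machinery under its own assumptions, not robustness to the
violations real transcriptome data bring.

## Numerical and design choices

* Convergence: `nlminb` with relative tolerance 1e-10 (likelihood changes
  well below 1e-6 at the optimum), up to two jittered restarts if the first
  attempt does not converge. Seeds control all randomness, including
  restarts.
* Branch lengths: a single ML scale on the fixed input topology per
  orthogroup rather than per-branch re-optimisation; with trees given in
  substitutions/site this recovers \(\omega\), \(\kappa\) and \(k\)
  accurately in simulation and keeps a full study run in minutes.
* A per-fit cache of spectral decompositions keyed by \((\kappa, \omega)\)
  exploits the one-coordinate structure of finite-difference gradients.
* Orthology recovery is scored on species composition: when a species
  retains both copies of a recent duplication, either copy is a valid
  representative, so tip-identity recovery is unidentifiable in principle.
* Degenerate inputs: zero-length branches give identity kernels; alignments
  reduced below 4 taxa are rejected with a reason code rather than an error;
  k hitting its bounds \([10^{-3}, 50]\) flags the fit as non-informative.
* `run_study()` defaults to the branch-model scan plus both branch-site and
  selection-intensity contrasts; the acceptance workflow runs the
  branch-model scan over the full 80-orthogroup study (the group-level
  Kruskal–Wallis conclusions depend only on it) and exercises the mixture
  families on dedicated simulation batches, keeping a complete run on one
  CPU within minutes.

## Worked example

```{r}
library(selcontrast)

dir <- tempfile("study")
generate_study(study_design(seed = 20), dir)
res <- run_study(dir, models = c("m0", "branch3"), seed = 1)

# group-level contrast on single-omega estimates
res$stats$kw_groups
tapply(res$branch$omega_m0, res$branch$group, median)

# one orthogroup in detail: selection-intensity contrast
study <- load_study(dir)
aa <- read_fasta(file.path(dir, "ogs", "og001.aa.fasta"))
cds <- read_fasta(file.path(dir, "ogs", "og001.cds.fasta"))
sc <- read_column_scores(file.path(dir, "ogs", "og001.scores.tsv"))
og <- prepare_orthogroup("og001", aa, cds, sc, study$species_lt)$og
m0 <- fit_single_omega(og)
r0 <- fit_relax(og, "absent", fix_k = 1, m0 = m0)
r1 <- fit_relax(og, "absent", m0 = m0, init = r0)
lrt(r0, r1, df = 1)
```

## Known limitations

* Branch lengths are scaled, not re-optimised per branch; orthogroups whose
  true branch lengths deviate strongly from the species tree's proportions
  will absorb the misfit into \(\omega\).
* Site flagging is naive empirical Bayes; with few foreground branches the
  posterior is optimistic relative to methods that integrate over parameter
  uncertainty.
* The 2-df branch-site LRT (the published convention) is conservative
  relative to the 1-df reference under the usual boundary asymptotics; both
  p-values are reported.
* No codon models beyond the GY94 family (no mutation-selection models, no
  empirical exchangeabilities), and no FASTQ/SAM/VCF input.
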