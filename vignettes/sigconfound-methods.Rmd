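---
title: "Methods: disentangling antipsychotic-drug and disease effects in bulk brain transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disentangling antipsychotic-drug and disease effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nearly all schizophrenia (SCZ) patients whose postmortem brain tissue enters
transcriptome studies were exposed to antipsychotic drugs (APDs), so
case-control differential expression confounds disease biology with drug
effects. `sigconfound` implements an analysis strategy for separating the
two: stratify cases by postmortem toxicology (APD-negative, atypical-positive,
typical-positive, mixed), summarize each sample's expression by a scalar
*disease expression signature*, and compare the signature across toxicology
subgroups; in parallel, compare human case-control co-expression against a
drug-exposure dataset (healthy primates given clozapine or haloperidol) via
signed consensus co-expression modules, classifying each module as
*convergent* (drug and disease move it in the same direction) or *divergent*
(opposite directions). Reference-based cell-type deconvolution asks whether
inferred cell-type shifts track diagnosis or drug exposure.

Because the motivating cohorts are access-controlled, the package ships a
synthetic-data generator that emulates their statistical structure; every
claim the test suite makes is a claim about behavior on those synthetic
conditions.

## The signature score

For a case-control contrast, per-gene log2 fold changes ("betas") are
estimated by (optionally weighted and empirical-Bayes moderated) least
squares on covariate-corrected logCPM residuals. Each sample `s` is then
scored by the dot product over all genes with nominal `p < 0.05`:

```
score_s = sum_g residual[g, s] * beta_g
```

A higher score means expression deviating from the cohort mean in the
disease direction. Scores are in arbitrary (beta-weighted logCPM) units;
only comparisons between samples are meaningful. Two properties matter for
interpretation:

* the score is linear in the residual matrix, so group contrasts of scores
  inherit the covariate correction applied to the residuals;
* by default betas and scores are computed on the *same* samples, which is
  how such aggregate scores are usually built but is mildly circular;
  `signature_scores_loo()` provides a leave-one-out variant in which each
  sample is scored on betas refit without it. The default is kept because
  the scientific claim is about *relative* subgroup ordering, which the
  circularity shifts but does not reorder.

Group comparisons follow a Shapiro-Wilk gate (`normality_gate()`): score
distributions are typically non-normal, so the battery is Kruskal-Wallis
across all groups, Kruskal-Wallis within case subgroups, Mann-Whitney U for
case versus control, and Dunn post hoc pairwise z tests with tie correction.
Dunn p-values are BH-adjusted across pairs; BH was chosen (over Bonferroni)
for consistency with the multiplicity control used everywhere else in the
pipeline, and is configurable.

## Preprocessing and covariate handling

The preprocessing chain is the standard bulk RNA-seq stack: CPM filtering
(`CPM > 1` in at least 50% of samples for the large human-like cohort, at
least 3 samples for the small primate-like one — one operation, two
presets), TMM scale factors (edgeR's implementation, trim fractions 0.3 /
0.05), `logCPM` with prior count 0.5 via
`log2((count + 0.5) / (lib * factor + 1) * 1e6)`, gene-centered PCA
(no unit-variance scaling, the convention for logCPM), and single-pass
outlier removal: a sample is dropped when its standardized score exceeds 5
SD in two or more of the top 20 PCs (3 SD for the small cohort). The
two-PC requirement makes the rule deliberately conservative: a sample
extreme along a single component survives.

Covariates enter in two modes. In *fixed* mode the design is predetermined
(large cohort: library batch, sex, age, effective mapping rate, intergenic
rate, RIN, PMI, pH; small cohort: batch, sex, mapping rates, RIN). In
*data-driven* mode, `select_covariates_sequential()` greedily adds the
candidate whose minimum Bonferroni-adjusted p across the top 20 PCs is
smallest (continuous candidates: Pearson test; categorical: one-way ANOVA),
regresses it out, recomputes the PCA, and repeats until nothing is
significant at `alpha = 0.05`. Where the procedure was underdetermined we
chose: Bonferroni over the 20 PCs per covariate (conservative and
deterministic), lexicographic tie-breaking, and PCA recomputation between
iterations (`recompute_pcs = TRUE`, the most literal reading of sequential
regression of collinear covariates; the cheaper fixed-PC variant is a
flag). Collinear duplicates can never be selected twice because the
accumulated design is rank-checked before each addition.

Residualization is per-gene (weighted) least squares; residuals are exactly
orthogonal to the design under the weights used. Missing covariate values
are a hard error — imputation would silently change the correction.

## Co-expression: consensus modules and convergence

Networks are *signed*: `a_ij = ((1 + cor_ij) / 2)^12`, so anticorrelated
genes get near-zero adjacency instead of being folded together; the soft
power 12 and all module parameters (minimum size 30, merge height 0.25,
minimum kME 0.3) are the field-standard values for signed networks. The
topological overlap matrix (TOM) combines direct adjacency with shared
neighbors. For two datasets on one-to-one orthologs, the second TOM is
rescaled so its 0.95 off-diagonal quantile matches the first's (the exact
quantile is configurable; 0.95 is the common default) and the consensus is
the element-wise minimum — a module must be supported in *both* species.

Module detection replaces the field's dynamic-hybrid tree cut with a
documented simplified procedure: the average-linkage
merge tree of `1 - consensusTOM` is traversed bottom-up; a subtree is
claimed as a module when it first reaches the minimum size and its mean
internal similarity exceeds twice its mean similarity to the rest of the
network; a claimed module keeps absorbing later joiners while their mean
similarity to it stays above half its internal mean, and freezes at the
first loose joiner. This handles modules that assemble at different heights
(which no single global cut height can) while remaining a few dozen lines
of auditable code. The published parameters are honored exactly downstream:
clusters below 30 genes are unassigned, module pairs whose eigengenes
correlate above 0.75 in *both* datasets are merged, and genes with signed
kME below 0.3 in either dataset (strict consensus reading; an "either"
mode exists) are unassigned. There is no exact analog of `deepSplit = 2`
in this scheme; the cohesion and join thresholds (2 and 0.5) play the
corresponding role and are exposed as arguments.

Eigengenes are unit-variance first principal components of the module's
gene-standardized expression, oriented so the mean correlation with member
genes is non-negative — a deterministic sign is required for the
convergence calls. Associations are per-module OLS of the eigengene on a
condition indicator (diagnosis in the case-control dataset, each treatment
versus placebo in the drug dataset), BH-corrected across modules within
each condition level. A module is *convergent* for a (diagnosis, treatment)
pair when the two t statistics share a sign and both reach `|t| >= 2`
(about two-sided p < 0.05 at these sample sizes; the threshold is explicit
and configurable rather than tied to a significance-star convention),
*divergent* when the signs differ at the same
magnitude, *indeterminate* otherwise.

## Deconvolution

`estimate_proportions()` is a transparent reference-based estimator in the
spirit of the assay-shift-correcting tools used for brain bulk data
("Bisque-like", not a re-derivation of any published estimator): per
sample, non-negative least squares of the bulk CPM vector on CPM-scaled
cell-type mean profiles over all shared genes (no marker pre-selection),
renormalized to the simplex. Renormalizing after NNLS rather than solving
with an equality constraint is simpler and identical on noiseless input.
When samples profiled in both bulk and reference exist, gene-wise linear
moment matching (shift/scale of bulk expression to the reference-composite
distribution estimated on the overlap) is applied first, absorbing
platform differences between the bulk and single-nucleus assays. Reference curation (merging
vascular subtypes, dropping stray clusters) is expressed as a merge map
and drop list. Proportion group tests reuse the non-parametric battery
with BH across cell types per test family.

## Enrichment

Gene-set enrichment is the classic two-sided Fisher's exact test (p by
summation of hypergeometric probabilities no larger than the observed
table's), with all expressed genes as background, restricted to one-to-one
orthologs for module enrichment. Sets overlapping a list in fewer than 4
genes are excluded *before* BH; applying the filter before adjustment was
chosen because it reduces the multiplicity denominator (the order is a
genuine design choice; the alternative is a flagged one-liner). The reported odds ratio is
the sample OR `ad/bc` (`Inf` when `bc = 0` with `ad > 0`; `0` when
`ad = 0`), not the conditional MLE.

## The synthetic generator

`simulate_bulk_cohort()` emulates the toxicology-stratified cohort: 113
controls and case subgroups of 23 (APD-negative), 28 (atypical), 27
(typical) and 10 (mixed); negative-binomial counts (dispersion 0.15) with
gene-wise baseline abundances, log-uniform library sizes of 10-30 million
(realistic bulk RNA-seq depth — at the `CPM > 1` filter boundary this
implies tens of supporting reads, which matters for co-expression
stability); log-scale covariate effects for sex, age, RIN, PMI, pH and
batch; and a planted disease effect of `base_lfc = 1` (log2) on 10% of
genes, scaled per subgroup by 1.5 (atypical), 1.2 (mixed), 1.0 (negative)
and 0.8 (typical) — the ordering the signature analysis is designed to
resolve, as the default planted truth. Planted outliers are displaced
along the first two PC directions of the noise-free mean structure,
because a displacement along one arbitrary direction surfaces on a single
PC and would (correctly) not be flagged by the two-PC rule.

`simulate_paired_species()` adds a drug-treatment dataset
(placebo/clozapine/low-dose haloperidol/high-dose haloperidol, 7/9/10/7)
sharing planted module membership across a one-to-one orthology;
per-module condition effects are signed independently per dataset, so
convergent and divergent modules are planted by construction. Within-module
correlation defaults to 0.6 (strong but realistic for brain co-expression
modules). The module-recovery checks use 5 planted 50-gene modules among
600 genes with nuisance covariate effects switched off — a low-noise
condition in which detection failures indicate algorithmic faults, not
power limits — and treatment effects of ±4 latent-SD, sized so eigengene
associations are unambiguous (|t| around 4) at n = 33. With the nuisance
covariates on, genes loading on shared demographic covariates form genuine
co-expression structure in each dataset, and a handful of such genes can
assemble into small additional consensus modules; that behavior is
realistic, and is the reason the low-noise condition exists for the
recovery checks.

`simulate_reference()` builds a single-nucleus-like reference (3 cell
types, 50 cells each, type-exclusive markers) and bulk mixtures with known
proportions; cases carry a planted 5-percentage-point decrease in
inhibitory neurons with a matching increase in excitatory neurons,
mirroring the cell-type question the deconvolution addresses. With
`noise = FALSE` bulk columns are exact convex combinations, supporting
exact-recovery tests.

What the generator does *not* emulate: gene-length and GC biases, batch
effects that correlate with diagnosis, ancestry structure, isoform-level
variation, dropout structure of real single-nucleus data, and dependence
between covariates. Passing tests therefore demonstrate correctness of the
machinery under the assumed model, not robustness to these real-data
pathologies.

## Numerical conventions and problem sizes

All randomness flows from one seed through fixed per-stage sub-seeds, so
every output (and the pipeline's JSON manifest, which records MD5 digests
of all intermediates) is byte-identical across reruns. Output tables carry
6 significant digits. Degenerate cases have documented conventions:
zero-residual-variance genes get `p = 0` (nonzero beta, flagged) or
`p = 1`; an all-tied Kruskal-Wallis returns `H = 0, p = 1`; Mann-Whitney
uses exact enumeration below 20 per group without ties and the
tie-corrected normal approximation with continuity correction otherwise;
noiseless eigengene fits cap `|t|` at 1e6.

The simulation-based checks run at deliberately modest problem sizes —
500-2000 genes, the cohort's 201 samples, 10-20 replicate seeds — chosen
so the whole suite completes in about a minute while leaving the empirical
rates (type-I error ~5%, ordering recovery, ARI, deconvolution MAE) stable
to the second digit. The same conditions at larger gene counts behave
identically; the statistics operate per gene or per module and gain
nothing from more genes beyond tighter rate estimates.

## Known limitations

* The simplified module cut is not the published dynamic-hybrid algorithm;
  very close or strongly overlapping modules that the hybrid PAM stage
  would separate may merge or shed members here.
* The deconvolution estimator is a transparent NNLS core; it will not
  reproduce the numerical output of any specific published tool, and rare
  or highly collinear cell types are not resolvable.
* Signature scoring inherits the circularity of its design unless the
  leave-one-out mode is used.
* The voom-style precision weights are only approximately constant for
  homogeneous genes (lowess jitter of a few percent is expected).
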