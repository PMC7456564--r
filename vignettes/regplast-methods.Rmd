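---
title: "Methods: regulon inference and regulatory plasticity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon inference and regulatory plasticity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regplast)
```

regplast implements a multi-stage inference chain for identifying a
transcriptional program — such as an epithelial differentiation program in
glioma — from expression data, and for prioritizing its driver regulators.
This vignette documents the models, the tunable parameters, the numerical
conventions, and the design choices made where the procedure was genuinely
open. Every stage is paired with a synthetic-data generator that plants the
quantity the stage is supposed to recover, so the whole chain is testable by
parameter recovery.

## Network inference and regulon construction

Candidate genes are prefiltered by pairwise Pearson correlation:
`pearson_prefilter()` keeps genes with at least one partner whose signed
correlation exceeds the threshold (default `r_threshold = 0.8`). The signed
convention is deliberate — a gene whose only strong partner is anticorrelated
is dropped — with `use_abs = TRUE` as the alternative. Constant genes have
undefined correlation and never pass.

`infer_network()` follows the tree-ensemble recipe: for every target gene, a
randomized regression forest predicts the target from all candidate
regulators except itself, and the importance of a regulator–target edge is
the impurity (variance) reduction credited to that regulator, averaged over
trees. Each target is standardized to unit variance before fitting so that
importances are comparable across targets; that standardization is the only
normalization applied. Defaults: 1000 trees per target and `sqrt(p)`
candidate regulators per split, the conventional forest settings. The forest
itself is fitted by the `ranger` engine with a per-target seed; samples are
internally ordered by identifier, so results are invariant to column
permutations of the input. Zero-variance targets are skipped and
zero-importance edges omitted.

`threshold_edges()` keeps the top fraction (default 1%) of edges by
importance. The fraction is computed over the *emitted* (nonzero-importance)
edges, not over all possible regulator–target pairs; the emitted set is what
the inference actually ranks, and the all-pairs denominator would make the
retained count depend on matrix size rather than on inference output. Ties
at the cut are broken by (regulator, target) lexicographic order so the
retained set is reproducible. `build_regulons()` then groups edges by
regulator and keeps regulators with at least `min_targets` (default 10)
targets.

## Regulon clustering and role deconvolution

TF–TF connections (`build_tf_graph()`) are weighted either by the Jaccard
index of target sets (default) or by summed direct-regulation importance.
`cluster_regulons()` performs average-linkage hierarchical clustering on the
distance `1 - weight / max(weight)`, cut at a user-chosen `k` (use `k = 8`
to mirror an eight-program decomposition) or, when `k` is omitted, at the
cut maximizing mean silhouette width over `k` in `2..min(10, n - 1)`. A
connected-components mode is available for block-structured graphs. Both
modes are deterministic; hierarchical merges inherit `hclust` tie handling,
and cluster labels are renumbered in order of first appearance so labelings
are stable under node reordering.

Role deconvolution formalizes the split of a program into *upstream
regulators* and *end targets* as a purely structural rule: within a cluster
(members = its TFs plus their thresholded targets), a member is an upstream
regulator iff it is the TF of a regulon whose targets intersect the cluster;
everything else is an end target. The partition is exhaustive and exclusive
by construction. A gene targeted by TFs of several clusters is assigned to
the cluster whose incoming edge has the highest importance (ties to the
lexicographically smallest TF). This out-degree rule is a declared
formalization — deconvolution procedures in the literature are rarely
specified precisely — chosen because it is expression-free, deterministic
and exactly testable: on a noise-free planted cluster with 18 regulators and
37 pure targets the round trip through inference recovers the 18/37 split
exactly.

## Sample scoring and clinical association

`ssgsea_score()` implements the single-sample rank-weighted running-sum
enrichment statistic: per sample, genes are ranked by expression descending
(ties broken by gene id), and the score is the sum over positions of the
weighted in-set ECDF minus the out-set ECDF, the in-set step at position
`i` weighted by `(N - i + 1)^alpha` with `alpha = 0.25` by default. The
single-sample running sum was chosen over a kernel-density variant because
it is self-contained per sample and exactly checkable against a brute-force
evaluation of the formula (the suite verifies agreement to 1e-9). Being
rank-based, scores are invariant to monotone transforms of a sample's
expression; min–max normalization across samples is optional.

Group contrasts (`group_compare()`, `methylation_compare()`) use the
Mann–Whitney rank-sum test — exact enumeration when both groups have at most
eight untied observations, otherwise the tie-corrected normal approximation —
because the score distributions are not modeled. Multiple testing across
features uses Benjamini–Hochberg; scores of different gene sets are few and
left uncorrected. `quantile_groups()` labels the `floor(q n)` highest and
lowest scoring samples (default quartiles), ties at the boundary resolved by
sample id.

`cox_fit()` maximizes the Cox partial likelihood with Breslow tie handling
(log-likelihood tolerance 1e-9, at most 100 Newton–Raphson iterations) via
the `survival` engine, and reports per-exposure log hazard ratios with Wald
intervals. The suite checks the estimator against an independent grid search
over the written partial likelihood and verifies both recovery of a planted
coefficient and null confidence-interval coverage. Both continuous and
dichotomized exposures are supported; neither is privileged.

Peak–region overlap (`peak_overlap()`) counts intersections under 0-based
half-open semantics, so abutting intervals do not overlap; BED input is
interpreted in the standard convention.

## Single-cell prioritization

`cluster_cells()` centers genes, projects cells onto the top principal
components (default 10) and runs k-means with 25 random restarts, keeping
the best within-cluster sum of squares. Random restarts rather than
k-means++ seeding: with 25 restarts on PCA scores the initialization scheme
is immaterial for the well-separated subpopulations this stage targets, and
the base algorithm keeps the dependency surface small. `k` defaults to 3 but
is a parameter.

`dependency_scores()` ranks candidate regulators of a program by how much of
the program's pairwise coexpression is routed through each candidate: for
candidate g, the score is the mean over program pairs (i, j) of
`max(0, |r(i,j)| - |r(i,j|g)|)`, with `r(·|g)` the first-order partial
Pearson correlation given g. This partial-correlation reduction is this
package's declared formalization of "coexpression dependency" — chosen
because it is order-free, nonnegative, and exactly testable against the
textbook partial-correlation formula — not a reproduction of any particular
published variant. Constant genes are excluded with a warning; a singular
denominator (|r| = 1) contributes a conditional correlation of zero.

`connectivity_trajectory()` tracks the mean pairwise Pearson correlation of
a gene trio while samples with the lowest anchor-gene expression are removed
step by step: each step removes `ceiling(removal_fraction * n_current)` of
the *current* cohort (default 10%, matching the "remove the bottom 10% each
time" protocol; a fixed grid over the original cohort would shrink the
removal count differently). Ties in anchor expression are broken by sample
id. Recording stops before the cohort falls below `min_samples`. The
trajectory functions accept any floor down to 3, but analyses and the
acceptance checks use a floor of 30 samples, the conventional minimum for a
stable correlation estimate; correlations on smaller tails are dominated by
sampling noise. Connectivity is the signed mean of the three pairwise
correlations by default (`use_abs = TRUE` for the unsigned mean), since the
hypothesis under test is a positive regulatory circuit.

## Isoform calling from alternative promoter usage

The two-promoter gene model has 15 exon rows: `exon1..exon3` (specific to
the full-length TA transcript), `exon3prime` (the distinct alternative first
exon of the truncated dN transcript), and shared `exon4..exon14`. Modeling
the dN-specific first exon as its own row, rather than as partial usage of
exon 3, makes the call rule crisp: `call_isoform()` computes the mean signal
over TA-specific and dN-specific exons, calls `none` below a combined
`min_total` (default 1, expression units), and otherwise requires one signal
to dominate the other by a factor `dominance` (default 3). Cells passing
neither dominance condition — or, degenerately, both, which requires both
signals to be zero — are `ambiguous`. The defaults are conservative: they
make mutually exclusive isoform expression checkable rather than assumed.
The exon-to-promoter grouping is configurable because published heatmap
descriptions of "the first seven exons" do not pin down an exact mapping.

`exon_usage_test()` converts each cell to usage proportions (cell total = 1;
zero-total cells are excluded rather than imputed) and compares each exon
between groups by rank-sum with BH correction; an exon with constant
proportions is degenerate and reported with p = 1. `dependency_by_group()`
applies a strict `expression > threshold` filter (default 1.5 on a
log2(TPM+1) scale, strict inequality as conventionally printed) before
grouping dependency scores by isoform call.

## What the synthetic data emulate — and what they do not

- `generate_grn_truth()` / `simulate_bulk()`: a linear structural equation
  model. TFs are exogenous (own standard-normal noise plus a cluster-level
  latent factor, default sd 1, which gives the TF-clustering stage its
  signal); non-TF targets are weighted sums of their regulators plus
  Gaussian noise; decoy genes (default: as many as there are regulated
  genes, so prefiltering has something to remove) are pure noise. Planted
  TF-to-TF edges exist structurally but, TFs being exogenous, leave no
  expression footprint. Default problem size for network-recovery checks:
  8 TFs with 10 targets each, 40 decoys, 300 samples, noise sd 0.5,
  500 trees.
- `simulate_survival()`: exponential event times with hazard
  `h0 exp(beta * score)`; independent exponential censoring whose rate is
  tuned by bisection to the requested censoring proportion within 2
  percentage points.
- `simulate_single_cells()`: negative-binomial counts, equal-sized
  subpopulations, per-cluster marker blocks, and a named quartet
  (CD44/TP63/MET/MACC1) elevated only in one cluster. No library-size,
  batch, or doublet artifacts are modeled.
- `simulate_trio_dynamics()`: a sample-wise Gaussian copula in which the
  trio's equicorrelation rises linearly with the anchor's rank, from
  `rho_low` to `rho_high` (both must exceed -0.5 for a valid 3x3
  correlation matrix).
- `simulate_exon_usage()`: expressed exon entries are `1 + Gamma` (mean 5),
  bounded away from zero so that zeros arise only from dropout or
  non-expression; this is what makes the caller exact on dropout-free data.
- `simulate_methylation()`: per-feature beta values
  `logistic(-coupling * z + noise)`, strictly inside (0, 1).

All generators take an explicit seed, use a scoped RNG stream (the session
RNG is restored afterwards), and are bit-reproducible given the seed.

Passing recovery tests on these generators demonstrates that each stage
recovers what it is designed to recover under its stated model. It does not
demonstrate robustness to the things the generators deliberately omit:
nonlinear regulation, feedback loops with expressed TF-to-TF dynamics,
confounded cohort composition, scRNA-seq depth variation, or isoform
quantification uncertainty from read assignment.

## Problem sizes used by the automated checks

The test suite and the acceptance script run the recovery analyses at the
sizes stated above (300 bulk samples and 5 replicate networks; 20 replicate
clusterings; 50 Cox and dependency replicates plus 200 null fits; 20
trajectory and isoform replicates of 500 samples / 200 cells; 2000 null
replicates for test calibration). These sizes were chosen so that each check
has clear statistical resolution at desk scale.

## Known limitations

- The dependency statistic and the role-deconvolution rule are declared
  formalizations of verbally described procedures; other formalizations are
  possible and could rank borderline candidates differently.
- The tree-ensemble importance is a ranking device, not an effect size;
  thresholding at a top fraction inherits its scale arbitrariness.
- With strongly correlated TFs (shared latent factor), importance spreads
  across co-members; regulon membership is robust to this, edge-level
  attribution less so.
- The single-sample enrichment score is comparable across samples of one
  matrix but not across matrices without the normalization flag.
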