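---
title: "Deriving brain cell-type signatures and estimating proportions with cellsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving brain cell-type signatures and estimating proportions with cellsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cellsig)
library(dplyr)
```

## The problem

Bulk brain RNA-seq averages over a mixture of cell types, so both the
interpretation of differential expression and the discovery of marker
genes depend on disentangling cell-type-associated expression. `cellsig`
implements a coherent chain for this: per-dataset signature derivation,
cross-dataset consensus ranking, overlap statistics for comparing
signatures and coexpression modules, and SVD-based estimation of relative
cell-type proportions from bulk data.

Six major brain cell types drive the defaults — astrocytes (AST),
endothelial cells (END), microglia (MIC), neurons (NEU), mature
oligodendrocytes (MOL) and oligodendrocyte precursor cells (OPC) — but
every function accepts arbitrary label vocabularies.

## The three association measures

For a target cell type *t* with reference set *R(t)* (all other types;
MOL and OPC are mutually excluded from each other's reference because
their transcriptomes are too similar for the contrast to be informative):

* **Enrichment** compares *t* against all of *R(t)* pooled:
  `stat = log2(mean CPM in t) − log2(mean CPM in pooled R)`. A gene can be
  enriched in two cell types at once.
* **Specificity** is the *minimum* over r ∈ R(t) of the pairwise log2 fold
  change t vs r. It is high only when the gene is elevated against every
  other type, which is what one wants of a marker gene; by construction it
  is a lower bound on every pairwise fold change, and the package asserts
  this invariant in its tests.
* **Absolute expression** ignores other cell types: samples are quantile
  normalized (each column mapped onto the mean of the sorted columns; ties
  receive the mean of their target values), converted to RPKM with gene
  length (kb) and library size (millions), and averaged within the cell
  type; genes are also ranked within the type (1 = highest). The standard
  error of the mean is reported as the dispersion summary.

### Shrinkage

Raw fold changes explode for low-count genes. Both tested measures
therefore use a shrunken log2 fold change: every observation is augmented
by a pseudocount proportional to its sample's relative library size,

```
y*_s = y_s + p · N_s / mean(N),    N*_s = N_s + 2 p · N_s / mean(N),
```

with `prior_count` p = 10 by default, and group means are taken on the
augmented-CPM scale. With equal library sizes this reduces to
`log2((ȳ_a + p) / (ȳ_b + p))` — e.g. group means 80 vs 5 give
`log2(90/15) = log2 6 ≈ 2.585` — and |logFC| is monotone non-increasing in
p, which the acceptance checks verify gene-by-gene on simulated data.
The same convention (prior scaled by relative library size, effective
library inflated by twice the prior) is used by the predictive-fold-change
shrinkage popular in count-based differential expression; an exact
numerical match to any external implementation is not part of the
contract, the augmentation formula above is.

Shrinkage couples the tested measures to absolute expression by design:
among genes with the same true ratio, the better-expressed one gets the
larger shrunken estimate, which is the desired behaviour when ranking
candidate markers. The trade-off between highly specific/low expression
and less specific/high expression markers is governed by `prior_count`;
we keep 10 as the default and expose it in `norm_params()`.

### Filtering and testing

Genes are first filtered by `filter_expressed()`: kept iff the arithmetic
mean of raw counts within at least one cell type is ≥ `min_mean_count`
(default 5, boundary inclusive). P-values come from a per-gene
negative-binomial likelihood-ratio test of the target-vs-reference
indicator on the log scale with the log library size as offset and any
per-sample covariates (e.g. total detected features) as additive terms.
Dispersion is estimated per gene by a degrees-of-freedom-corrected
method-of-moments estimator, then shrunk (70% weight) toward a loess trend
of log-dispersion on log-mean across genes, and held fixed in both model
fits. This is deliberately lighter machinery than quasi-likelihood
pipelines; the property it must deliver — empirical type-I error of the
raw test within [0.02, 0.10] at nominal 0.05 on null simulations, and zero
genes passing the volcano thresholds (BH-adjusted p < 0.05 *and* fold
change ≥ 4, the FC boundary inclusive) — is verified by the test suite on
2000-gene null simulations, where it lands near 0.05.

The specificity p-value is taken from the pairwise contrast that attains
the minimum fold change (the measure itself is a fold-change statistic; a
p is reported for table completeness). Ranks anywhere are deterministic:
ties break by (statistic descending, gene id ascending).

A design note on quantile normalization: the expression measure
normalizes **raw** counts, before any augmentation — shrinkage is a device
for fold-change estimation, not an expression estimate.

## Consensus across datasets

`dataset_signatures()` stacks per-dataset tables, case-folding gene
symbols so human (upper-case) and mouse (title-case) tables intersect by
symbol; collisions created by the folding are warned about and surfaced,
never silently merged, and when a matrix is harmonized the first
occurrence wins. Orthology mapping beyond symbol equality is out of scope.

`build_consensus()` aggregates one cell type and measure:

* enrichment/specificity: the per-dataset log2 fold changes are combined
  by the median (default) or the mean, selectable via `agg`. Both are
  offered because the two natural summaries genuinely differ in
  robustness; the median is the default as the more outlier-resistant
  choice. Aggregation is on the log scale, keeping up- and
  down-regulation symmetric.
* absolute expression: within-dataset, within-cell-type expression ranks
  are combined by their grand median, regardless of `agg`.

The presence rules: a symbol must appear in **strictly more than half** of
the in-scope datasets (so 3 of 5 qualifies, 2 of 4 does not), in-scope
meaning datasets that contain the cell type at all — a type absent from a
dataset neither contributes nor counts in the denominator. In the combined
scope the symbol must additionally appear in at least one human and one
mouse dataset; this cross-species rule is applied uniformly to all three
measures, and only when both species are actually present in scope, so a
single-dataset run degenerates gracefully to that dataset's own ranking.
The full ordering is invariant to dataset input order (ties break by
presence count, then symbol).

## Overlap statistics

`fold_enrichment()` implements the observed-over-expected intersection
size for two sets in a universe, with the hypergeometric upper tail as the
p-value (the natural exact test for a pairwise overlap). The universe for
signature comparisons should be the symbols common to the compared
datasets; for module overlaps the union of genes in either network's
input.

`multiset_enrichment()` generalizes to k sets:
`FE = |∩Dᵢ| / (∏|Dᵢ| / |U|^(k−1))`. The null distribution of the
intersection size under independent uniform draws of each set's size is
computed exactly by folding one hypergeometric per set (the intersection
of a current intersection of size m with a new random set is
hypergeometric), used by default for k ≤ 5; larger k falls back to seeded
Monte Carlo with the (r+1)/(n+1) estimator.

`fisher_enrichment()` runs 2×2 Fisher's exact tests of a query set against
annotation sets with BH across sets; unbounded odds ratios are reported as
`Inf`. `module_overlap()` computes the all-pairs matrix between two module
collections using one-sided (enrichment-direction) tests, BH-adjusted
jointly over the full matrix — joint adjustment is the stricter of the
plausible conventions and is stated here as the package's choice — and
summarizes each column by the proportion of row modules it significantly
overlaps (the column-normalization convention: denominator = number of
row modules).

## Proportion estimation and deconvolution

`select_markers()` takes the top-n specificity-ranked genes per cell type
(default n = 50), after intersecting with the genes present in the bulk
matrix — so a platform measuring only part of the genome simply yields a
shorter, order-preserved list with a warning. Markers appearing in two
cell types' lists are kept in both and warned about.

`estimate_proportions()` implements the CellCODE-style surrogate
proportion variable: subset the bulk matrix to a cell type's markers,
z-scale each gene across samples (`scale_genes = TRUE` by default;
exposed because scaling is the one genuinely open choice in this
construction), and take the first right singular vector. The SVD's sign is
arbitrary, so the SPV is flipped, when necessary, to correlate positively
with the per-sample mean of the scaled marker rows; with the data negated
the reference negates too, and the corrected SPV mirrors exactly — the
correction makes the estimate deterministic, not invariant to sign
reversal of the input, which would be statistically wrong. SPVs have unit
Euclidean norm, are relative within a cell type across samples, and carry
no absolute-fraction meaning; no simplex constraint is imposed, and
constrained absolute-fraction deconvolution is deliberately out of scope.

Why ~50 markers? A single marker gene is hostage to its own stochastic
expression; averaging over dozens of markers suppresses that noise, while
going far beyond the well-ranked markers dilutes the signal with weaker
genes. `cumulative_marker_curve()` makes the trade-off visible by
computing the SPV from the top 2, 3, …, n markers against a per-sample
reference (simulated truth, or an orthogonal quantification such as
immunohistochemistry), alongside each marker's individual correlation;
small marker sets can even flip the estimate's sign when an early marker
anticorrelates, a failure mode the curve exposes and larger sets resolve.
With fewer measured genes, ~25 markers is a reasonable fallback.

`adjust_expression()` removes composition effects: each gene is regressed
on all SPVs plus an intercept by OLS and replaced by its residual plus its
mean. Residuals are exactly orthogonal to the SPVs (the tests require the
maximum absolute correlation to be below 1e-8), genes orthogonal to the
SPVs pass through unchanged, and the operation requires more samples than
SPVs plus intercept.

Bulk input is assumed already normalized, preferably log-scale (e.g. log2
CPM/FPKM); the estimator only warns when the input looks like raw counts
(all integers with a large maximum) rather than re-normalizing behind the
user's back.

## The simulators

`simulate_cells()` draws a negative-binomial world: gene baseline means
log-normal across genes (sdlog = 1 around `baseline_mean`, default 20 —
a realistic right-skewed expression distribution), disjoint marker blocks
per cell type boosted by `2^marker_log2_effect` (default 4, a strong but
realistic marker effect), log-normal library-size factors with CV 0.3,
and NB size `dispersion` = 10 (moderate overdispersion). Defaults simulate
50 cells per type for six types and 50 markers per type; 1000 genes keep
the test surface fast. `simulate_bulk()` mixes the per-type expected
profiles with Dirichlet(α = 1) proportions over 40 samples and adds NB
noise around the expectation; `noise = FALSE` returns the exact convex
combination, and one-hot proportions reproduce a profile column exactly.
All generators are pure functions of (config, seed).

What the simulators do **not** emulate: dropout/zero inflation (off by
default; a `dropout` rate exists for stress tests only), cell-type
sub-structure, batch effects, and gene–gene correlation beyond the mixing
structure. Passing tests on this surface demonstrates the estimators'
correctness under their own model assumptions, not robustness to every
real-data pathology. One such pathology is visible even inside the model:
when strong markers occupy a large fraction of the genome, they inflate
their own cells' library sizes and CPM-scale fold changes are compressed
below the planted effect (a composition effect that TMM-style
normalization would counter; TMM is out of scope here). The effect-size
recovery test therefore plants markers as a small genome fraction, while
ranking-based recovery is insensitive to the compression.

## Numerical choices and degenerate inputs

* Dispersion estimates are clamped to [1e-4, 5]; all-zero genes get p = 1.
* Quantile normalization of a single sample is the identity.
* A constant marker submatrix is an error ("degenerate markers");
  individual constant marker genes are dropped with a warning before
  scaling.
* A constant reference vector makes correlations undefined; the curve
  reports them as `NA` with a single warning.
* Empty sets get fold enrichment 0 with p = 1 and a warning rather than
  NaN.
* Monte Carlo p-values never return 0 (the +1 correction).
* Problem sizes in the test suite and acceptance script — 2000-gene null
  simulations, 20 bulk mixtures of 40 samples, 1000-gene recovery runs —
  were chosen as the smallest sizes at which the distributional
  properties under test are stable.

## Pipeline and reproducibility

`read_run_config()` validates a YAML run configuration (unknown keys
rejected; file existence and the MOL/OPC reference exclusion checked, all
problems reported together). `run_signatures()` writes one TSV per
(dataset, cell type, measure) plus a run log echoing every threshold
applied; `run_pipeline()` chains signatures → consensus → marker selection
→ SPV estimation → adjustment, writes every stage's output, and a
manifest (inputs, parameters, seed, package version) sufficient to
reproduce the run; reruns are byte-identical. A markers file without
datasets switches to bulk-only mode, skipping derivation.

## Known limitations

* Cross-species matching is by case-folded symbol only; ambiguous
  human–mouse symbol pairs are surfaced as collisions, not resolved.
* The NB test trades exactness for speed and transparency; its size is
  verified empirically rather than guaranteed analytically.
* SPVs are relative; comparing SPV magnitudes *between* cell types is not
  meaningful.
* Consensus reproduction of any published marker list requires the
  original datasets; the package ships only synthetic fixtures.
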