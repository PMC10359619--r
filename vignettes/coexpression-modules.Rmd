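---
title: "Weighted co-expression network modules with coexmods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted co-expression network modules with coexmods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmods)
```

## The model

Co-expression analysis treats the pairwise correlation structure of a
samples-by-genes expression matrix as a weighted network and looks for
*modules*: groups of genes whose expression rises and falls together across
samples, typically because they share regulation or cell-type context. The
pipeline implemented here is the classic weighted-network recipe:

1. **Correlation.** Pairwise Pearson correlation (or the outlier-robust
   biweight midcorrelation) between all gene pairs. Correlation is
   scale-sensitive: the package accepts any numeric expression scale and
   deliberately performs no normalization — inputs are expected to be
   normalized and batch-corrected beforehand.
2. **Soft thresholding.** Correlations become edge weights through a power
   transform. For a correlation $r$ and power $\beta$ the *signed* network
   uses $a = ((1+r)/2)^\beta$, the *unsigned* network $|r|^\beta$, and the
   *signed-hybrid* network $r^\beta$ for $r>0$ and $0$ otherwise. Raising to
   a power suppresses weak, noise-dominated correlations smoothly instead of
   imposing a hard cutoff. The power is chosen as the smallest candidate for
   which the network's degree distribution is approximately scale-free
   (signed $R^2$ of the log–log degree fit at least `fitCutoff`, default
   0.9, over equal-occupancy connectivity bins).
3. **Topological overlap.** The adjacency is smoothed into the topological
   overlap matrix
   $$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}},$$
   which scores two genes as similar when they share neighbors, not merely
   when they are directly connected. $1 - \mathrm{TOM}$ is the clustering
   dissimilarity.
4. **Module detection.** Average-linkage hierarchical clustering of the TOM
   dissimilarity followed by an adaptive ("dynamic") cut of the dendrogram,
   described below. Genes in no module carry label 0, rendered grey.
5. **Eigengenes.** Each module is summarized by its eigengene: the first
   principal component of the module's standardized expression submatrix,
   scaled to zero mean and unit variance and sign-oriented to correlate
   non-negatively with the module's mean standardized expression. Modules
   whose eigengenes correlate above $1 - \texttt{mergeCutHeight}$ are merged
   and eigengenes recomputed, iterating to stability.

Downstream, eigengenes are correlated with sample traits (two-sided t test
on $t = r\sqrt{(n-2)/(1-r^2)}$, Benjamini–Hochberg adjusted across the whole
module-by-trait grid), genes are ranked within modules by kME (correlation
with the own-module eigengene) with intramodular connectivity breaking ties,
and module sets from different networks — or external marker-gene lists —
are compared by Jaccard index and one-sided Fisher's exact (hypergeometric
enrichment) tests over an explicit gene universe.

## The adaptive tree cut

Only the clustering tree is given; deciding which branches are modules is
the substantive algorithmic choice, and this package's variant is defined
normatively here (the same text as `?cutModules`):

* A base static cut at `cutHeight` (default 0.99 of the maximum merge
  height) yields candidate branches; branches smaller than `minModuleSize`
  dissolve into the unassigned label.
* Each candidate branch is split recursively at its top merges. A merge
  splits when both sub-branches hold at least `minModuleSize` features, are
  internally tight, and are well separated from the join. Tightness and
  separation are measured on the branch *core* — the $\max(\texttt{minModuleSize},
  \lceil\sqrt{n}\rceil)$ members with the lowest average within-branch
  dissimilarity — as the mean pairwise core dissimilarity (*core scatter*)
  and the difference between the join height and the core scatter (*gap*).
  Both are expressed as fractions of the distance between the cut height and
  the 5th percentile of merge heights. `deepSplit` (0–4, default 2)
  interpolates the maximum admissible core scatter through 0.64, 0.73, 0.82,
  0.91, 0.95, with the minimum gap set to $3/4\,(1 - \text{maxCoreScatter})$:
  larger values split more aggressively into smaller, tighter modules.
* A merge joining a branch smaller than `minModuleSize` onto a larger one
  absorbs the small branch when its join height sits within the minimum gap
  of the large branch's core scatter (the signature of a module assembling
  gradually), and sends it to the unassigned label otherwise (the signature
  of an outlier attaching high in the tree).
* With `pamStage = TRUE` (default), each unassigned feature is rescued into
  the module with the smallest average dissimilarity, provided that beats
  the feature's average dissimilarity to all features. All rescue decisions
  are taken against the pre-rescue assignment, so the result does not depend
  on feature order.

Deliberate consequences of this design: the recursion prefers to oversplit
when branch geometry is ambiguous, because fragments of one true module have
near-collinear eigengenes and are re-fused by the merge stage
(`mergeCutHeight` 0.25 by default, i.e. eigengene correlation 0.75), whereas
a missed split cannot be repaired downstream. A tie between the largest
sample clusters in outlier removal, by contrast, is a hard error rather than
an arbitrary choice — silent sample removal is unacceptable in QC.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `networkType` | signed | correlation-to-adjacency transform; signed keeps anti-correlated genes apart |
| `power` | auto (scale-free fit, cutoff 0.9; candidates 1–10, 12–20) | soft threshold $\beta$ |
| `corMethod` | pearson | `bicor` downweights outlier samples per gene pair |
| `tomType` | signed | recorded variant; numerically identical for the non-negative adjacencies produced here |
| `minModuleSize` | 30 | smallest admissible module (community convention) |
| `deepSplit` | 2 | split aggressiveness, 0–4 |
| `cutHeight` | 0.99 | base static cut as fraction of the top merge height |
| `pamStage` | TRUE | rescue of unassigned features |
| `mergeCutHeight` | 0.25 | eigengene dissimilarity below which modules merge |
| `minTotalExpression` | 1 | feature QC: minimum summed expression |
| `maxMissingFraction` | 0.5 | feature QC: maximum fraction of entries that are missing or $\le 0$ |

The QC defaults suit non-negative abundance data (counts, TPM). For data on
a centered scale — including this package's own simulations — the
sparsity rule would discard roughly half the features; pass
`minTotalExpression = -Inf, maxMissingFraction = 1` to disable abundance QC,
as the pipeline examples do. Sparsity counts both missing and non-positive
entries, so the low-expression and sparsity rules are each independently
testable. The defaults above are package choices, documented as such and all
overridable; no universal values exist for them.

## The synthetic-data generator

`simulateExpression()` plants modules with a single latent factor each:
factor $f_m \sim N(0,1)$ per sample, features $x = \lambda f_m +
\varepsilon$ with $\varepsilon \sim N(0, \sigma^2)$ and $\lambda = \sigma
\sqrt{\rho/(1-\rho)}$, so the expected within-module correlation is exactly
$\rho$. Background features are pure noise; traits respond linearly (or
through a logistic threshold, for binary traits) to chosen factors with a
stated effect size; an optional shared-factor mode makes groups of modules
collinear to exercise the merge stage. One master seed drives every draw in
a fixed order, so identical designs are bit-reproducible.

What the generator does *not* emulate: count noise (negative binomial
mean–variance coupling), library-size and batch effects, correlated factor
hierarchies, or gene-length biases. Tests passing on these simulations
demonstrate that the network algebra, the cut, and the statistics behave as
specified under a controlled correlation structure — not that any particular
biological dataset will yield clean modules.

```{r simulate}
sim <- simulateExpression(simulationDesign(
    nSamples = 50, moduleSizes = c(100L, 100L, 100L), nBackground = 30L,
    withinModuleCor = 0.7, seed = 7L,
    traitLinks = data.frame(module = 1L, trait = "score", effect = 1,
                            type = "numeric")))
sim$dataset
```

```{r pipeline}
net <- buildNetwork(sim$dataset, power = 6)
det <- detectModules(sim$dataset, net)
det$modules
evaluateRecovery(sim$trueLabels, det$modules)$ari
```

```{r stats}
res <- moduleTraitCorrelation(det$eigengenes,
                              as.data.frame(sampleData(sim$dataset)))
head(res[order(res$padj), ])
```

## Numerical choices and degenerate inputs

* **Vectorized TOM.** With unit diagonal, $\sum_u a_{iu}a_{uj} =
  (A^2)_{ij}$ includes the $u=i$ and $u=j$ terms, each equal to $a_{ij}$,
  so the shared-neighbor sum is $A^2 - 2A$ off-diagonal — one matrix
  product instead of a cubic loop. The tests hold the vectorized result to
  the elementwise definition within $10^{-12}$.
* **Eigengene sign and rank.** Sign orientation follows the mean
  standardized module expression; singular values below $10^{-12}$ of the
  leading one are treated as zero, so a module of identical profiles
  reports a variance-explained fraction of exactly 1.
* **Tied merge heights.** Average linkage on block-structured data produces
  runs of numerically tied heights that `stats::cutree` refuses; static
  cuts are therefore computed with a union–find pass over the merge list,
  which tolerates epsilon jitter.
* **Scale-free fit degeneracy.** If all connectivities coincide, the
  log–log regression is undefined and the fit errors out explicitly rather
  than returning a fabricated $R^2$; empty or zero-frequency bins are
  dropped before the regression.
* **Fisher sidedness and universe.** Overlap tests are one-sided
  (enrichment) by default because the use-case is finding conserved
  modules; a two-sided option exists. The gene universe is a mandatory,
  logged parameter (union of both collections by default) since it changes
  p-values materially; the unassigned set is a comparable pseudo-module and
  is flagged so it can be excluded. The report filter keeps pairs with
  Jaccard strictly greater than the threshold.
* **Missing values** are accepted at ingestion, never silently
  pairwise-deleted: correlation refuses datasets with missing entries, and
  `filterFeatures()` is the supported resolution path.

## Problem sizes in the test bench

The bundled tests and the acceptance script run the full pipeline on
simulated datasets of 200–500 features and 40–50 samples (10 seeds per
condition for recovery claims, 1000 null trait draws for calibration,
roughly 630&nbsp;000 enumerated 2×2 tables for the exact-test oracle). These
sizes were chosen so that every claim is recomputed from scratch on each
run while keeping the whole bench in the minutes range; the algorithms are
dense whole-matrix operations whose cost grows cubically in the feature
count, and nothing in the implementation is specific to these sizes.

## Known limitations

* Whole-matrix in-memory computation: the dense correlation/TOM path holds
  three $p \times p$ matrices; tens of thousands of features are feasible
  on a workstation, but there is no blockwise or sparse path here.
* No consensus modules across multiple networks, no incremental sample
  addition/removal, and no functional-enrichment or protein-interaction
  queries — module gene lists export cleanly for external enrichment tools.
* The h5ad single-cell container is not read directly; export the matrix
  and annotations to CSV/TSV first.
* The tree-cut variant is this package's own normative definition. It
  matches the community defaults in spirit and parameter naming, but exact
  module boundaries can differ from other implementations on the same data.
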