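# coexmods

Weighted co-expression network modules for bulk and single-cell-derived
expression matrices, in R.

Given a normalized samples × genes expression matrix, `coexmods` finds
groups of co-expressed genes ("modules") with the weighted-network recipe:
pairwise correlation → soft-power adjacency → topological overlap matrix
(TOM) → average-linkage clustering with an adaptive (dynamic) tree cut →
module eigengenes. It then relates modules to sample traits, ranks hub
genes by module membership (kME), and compares module sets across networks
or against external marker-gene lists with Jaccard indices and one-sided
Fisher's exact tests. A planted-module simulator with linked traits serves
as the test bench for every stage.

It is aimed at transcriptomics practitioners who want the classic
co-expression pipeline as composable, validated R functions with explicit
parameters and deterministic outputs.

## The core quantities

For correlation *r* and soft power β, the signed adjacency is
*a* = ((1+*r*)/2)^β (unsigned |*r*|^β, signed-hybrid *r*^β for *r*>0 else
0). β is chosen as the smallest candidate whose degree distribution is
approximately scale-free (signed R² ≥ 0.9). The topological overlap

    TOM_ij = ( Σ_{u≠i,j} a_iu a_uj + a_ij ) / ( min(k_i, k_j) + 1 − a_ij )

with connectivity k_i = Σ_{u≠i} a_iu scores genes by shared neighborhood;
1 − TOM is the clustering dissimilarity. Each detected module is summarized
by its eigengene — the first principal component of its standardized
expression submatrix, unit-variance and sign-oriented — and module–trait
association uses t = r·sqrt((n−2)/(1−r²)) with Benjamini–Hochberg
correction across the whole module × trait grid. Module overlap between two
networks is tested against the hypergeometric tail over an explicit gene
universe.

## Worked example

```r
library(coexmods)

sim <- simulateExpression(simulationDesign(
    nSamples = 50, moduleSizes = c(100L, 100L, 100L), nBackground = 30L,
    withinModuleCor = 0.7, seed = 7L,
    traitLinks = data.frame(module = 1L, trait = "score", effect = 1,
                            type = "numeric")))
sim$dataset
#> CoexDataSet: 50 samples x 330 features
#>   sample annotations: score

net <- buildNetwork(sim$dataset, power = 6)
net
#> CoexNetwork: 330 features
#>   pearson correlation, signed network, power 6, signed TOM

det <- detectModules(sim$dataset, net)
det$modules
#> ModuleSet: 3 modules over 330 features
#>   unassigned (grey): 0
#>   sizes: turquoise=112, blue=110, brown=108

evaluateRecovery(sim$trueLabels, det$modules)$ari
#> [1] 0.8575854

res <- moduleTraitCorrelation(det$eigengenes,
                              as.data.frame(sampleData(sim$dataset)))
head(res[order(res$padj), ], 3)
#>   module trait       r        p     padj
#> 3      3 score  0.7117 6.89e-09 2.07e-08
#> 2      2 score -0.3035 3.22e-02 4.83e-02
#> 1      1 score -0.0838 5.63e-01 5.63e-01
```

The three planted modules are recovered exactly in count and essentially in
membership (the adjusted Rand index of 0.86 reflects background-noise genes
rescued into modules by the PAM stage; disable with `pamStage = FALSE`).
The trait planted on module 1 surfaces as the strongest association in the
table — it appears against detected module 3 because detected labels are
ordered by module size, not by planted index. A yaml-configured end-to-end
run (`runPipeline()`) writes the assignment, eigengene, QC, soft-threshold
and trait-correlation tables plus a config snapshot and log; a thin CLI
over the same functions lives at `inst/scripts/coexmods.R` with
`simulate`, `run` and `compare` subcommands.

Methods, parameter semantics, and the normative definition of the adaptive
tree cut are in the vignette: `vignettes/coexpression-modules.Rmd`.

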