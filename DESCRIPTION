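Package: coexmods
Title: Weighted Co-Expression Network Modules for Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies co-expression modules from gene or transcript
    expression matrices using the weighted co-expression network pipeline:
    pairwise correlation, soft-power adjacency, topological overlap,
    average-linkage hierarchical clustering with an adaptive (dynamic)
    tree cut, and module eigengene summarization. Downstream tools cover
    module-trait correlation, module membership (kME) and hub-gene
    ranking, and comparison of module sets across networks or against
    external marker-gene lists with Jaccard indices and one-sided
    Fisher's exact tests. A synthetic-data generator with planted modules
    and linked traits supports benchmarking and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mclust
biocViews: Network, GeneExpression, Clustering, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
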