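Package: circnet
Title: Circadian Transcriptome Network Analysis with Cosinor
    Rhythmometry and Evidence-Graph Centrality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for circadian gene expression contrasts in
    cultured fibroblasts: signed fold-change and 2^-ddCt arithmetic with
    significance filtering, a principal-component feature screen, single
    24-h cosinor fitting with a zero-amplitude F-test and polarogram
    export, assembly of a multi-evidence gene interaction hypergraph and
    its deterministic agglomeration into a weighted simple graph, five
    weighted topology indices with consensus ranking of central genes,
    closeness-scaled hierarchical clustering of fold-change profiles with
    hypergeometric gene-set over-representation, and a synthetic-data
    generator that emulates the study design with planted ground truth
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    fgsea,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
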