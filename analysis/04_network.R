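#!/usr/bin/env Rscript
# Stage 4 — evidence hypergraph assembly and agglomeration.
#
# Restricts the evidence table to the genes retained by the feature screen,
# assembles the signed multi-evidence hypergraph (node weights carry the
# fold-change profiles), agglomerates parallel evidences into single weighted
# edges via W_AB = exp(n) * mean(weights), and reports the global topology of
# the resulting network.

suppressPackageStartupMessages(library(circnet))

data_dir <- "results/data"
out_dir <- "results/network"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cm <- read_contrasts(file.path(data_dir, "contrasts.tsv"))
evidence <- read_evidence(file.path(data_dir, "evidence.tsv"))
retained <- readLines("results/expression/retained_genes.txt")

keep <- evidence$gene_a %in% retained & evidence$gene_b %in% retained
message(sprintf("%d of %d evidence rows connect retained genes",
                sum(keep), nrow(evidence)))

h <- build_hypergraph(evidence[keep, ], node_weights = cm,
                      unknown_genes = "drop")
multi <- sum(table(paste(h$edges$gene_a, h$edges$gene_b)) > 1)
message(sprintf("hypergraph: %d nodes, %d evidence edges; %d pairs with >1 evidence",
                length(h$nodes), nrow(h$edges), multi))

g <- agglomerate(h)
write_weighted_graph(g, file.path(out_dir, "weighted_graph.tsv"))

gs <- global_stats(g)
jsonlite::write_json(gs, file.path(out_dir, "global_stats.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf(paste("network: clustering coefficient = %.3f, connected components = %g,",
                      "diameter = %g, shortest paths = %g, characteristic path length = %.3f,",
                      "average neighbors = %.3f, density = %.3f, heterogeneity = %.3f"),
                gs$clustering_coefficient, gs$connected_components,
                gs$diameter, gs$shortest_paths_count,
                gs$characteristic_path_length, gs$avg_neighbors, gs$density,
                gs$heterogeneity))
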