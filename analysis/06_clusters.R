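#!/usr/bin/env Rscript
# Stage 6 — closeness-scaled clustering and gene-set enrichment.
#
# Scales each retained gene's signed fold-change profile by its closeness,
# clusters the scaled profiles hierarchically (squared Euclidean, Ward) into
# five groups, tests every cluster against the annotation sets by the
# hypergeometric upper tail with BH adjustment, and scores recovery of the
# planted cluster structure.

suppressPackageStartupMessages(library(circnet))

out_dir <- "results/clusters"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cm <- read_contrasts("results/data/contrasts.tsv")
truth <- read_truth("results/data/truth.json")
sets <- read_gmt("results/data/sets.gmt")
tt <- utils::read.table("results/topology/topology_table.tsv", sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
closeness <- stats::setNames(tt$closeness, tt$gene)

keep <- cm$genes %in% names(closeness)
cm_net <- contrast_matrix(cm$ratio[keep, , drop = FALSE],
                          cm$p_value[keep, , drop = FALSE])
profiles <- scale_by_closeness(cm_net, closeness)
cs <- hcluster_profiles(profiles, k = 5, linkage = "ward")

assign_df <- data.frame(gene = names(cs$assignment),
                        cluster = as.integer(cs$assignment))
utils::write.table(assign_df, file.path(out_dir, "clusters.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
ape::write.tree(ape::as.phylo(cs$tree), file.path(out_dir, "dendrogram.nwk"))
message(sprintf("clustered %d genes into %d groups (sizes: %s)",
                length(cs$assignment), cs$k,
                paste(tabulate(cs$assignment, cs$k), collapse = ", ")))

if (requireNamespace("mclust", quietly = TRUE)) {
  shared <- intersect(names(cs$assignment), names(truth$cluster_assignment))
  ari <- mclust::adjustedRandIndex(cs$assignment[shared],
                                   truth$cluster_assignment[shared])
  message(sprintf("adjusted Rand index against the planted clusters: %.3f", ari))
}

enr <- enrich_sets(cs, sets, universe = names(cs$assignment))
utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig <- enr[enr$significant, ]
message(sprintf("%d significant (cluster, set) associations; %d of %d clusters hit their planted set first",
                nrow(sig), sum(vapply(unique(enr$cluster), function(cl) {
                  sub <- enr[enr$cluster == cl, ]
                  min(sub$adjusted_p[grepl("^planted", sub$set)]) <
                    min(sub$adjusted_p[grepl("^decoy", sub$set)])
                }, logical(1))), length(unique(enr$cluster))))
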