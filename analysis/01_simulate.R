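#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# The raw data behind this analysis (pooled fibroblast RNA-seq libraries,
# serum-shock qRT-PCR series, the assembled interaction network) are not
# publicly deposited, so the workflow runs on synthetic inputs that emulate
# the study design: 5-contrast fold-change profiles with five planted
# clusters, 24-h cosine time series for seven clock genes in three conditions
# sampled at 1/4/10/16/22/28 h, a six-category evidence hypergraph with one
# planted hub, and matched gene-set annotations plus decoys. Ground truth is
# written alongside for the recovery checks in later stages.

suppressPackageStartupMessages(library(circnet))

seed <- 20260925L
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

message("simulating 190-gene contrast profiles with 5 planted clusters")
gcp <- gen_contrast_profiles(n_genes = 190, k_clusters = 5, noise_sd = 0.2,
                             seed = seed)
write_contrasts(gcp$matrix, file.path(data_dir, "contrasts.tsv"))

message("simulating the evidence hypergraph (6 categories, hub G0001)")
geh <- gen_evidence_hypergraph(gcp$truth$gene_ids, n_categories = 6,
                               edge_density = 0.024, hub_genes = "G0001",
                               hub_boost = 5, seed = seed + 1)
write_evidence(geh$evidence, file.path(data_dir, "evidence.tsv"))

message("simulating serum-shock time series for 7 clock genes x 3 conditions")
clock_genes <- c("ARNTL", "ARNTL2", "CLOCK", "CRY1", "PER1", "PER2", "PER3")
rp <- random_rhythm_params(clock_genes, noise_sd = 0.05, seed = seed + 2)
ts <- gen_timeseries(rp, n_replicates = 3, seed = seed + 3)
write_timeseries(ts$series, file.path(data_dir, "timeseries.tsv"))

message("building annotation sets (coverage 0.8) plus 10 decoys")
sets <- gen_annotation_sets(gcp$truth, coverage = 0.8, decoy_sets = 10,
                            seed = seed + 4)
write_gmt(sets, file.path(data_dir, "sets.gmt"))

truth <- gcp$truth
truth$hub_genes <- geh$truth$hub_genes
truth$rhythm_params <- rp
write_truth(truth, file.path(data_dir, "truth.json"))

message(sprintf("wrote %d genes, %d evidence rows, %d series points to %s",
                length(gcp$truth$gene_ids), nrow(geh$evidence),
                nrow(ts$series), data_dir))
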