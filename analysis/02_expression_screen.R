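#!/usr/bin/env Rscript
# Stage 2 — fold-change reporting and the PCA feature screen.
#
# Applies the sequencing significance threshold (p < 0.001) to each of the
# five contrasts, reporting up/down gene counts, then screens genes by how
# much they vary along the first three principal components of the
# standardized log2-ratio matrix, discarding the flattest half.

suppressPackageStartupMessages(library(circnet))

data_dir <- "results/data"
out_dir <- "results/expression"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cm <- read_contrasts(file.path(data_dir, "contrasts.tsv"))

for (ct in cm$contrasts) {
  res <- filter_significant(cm, ct, alpha = 0.001)
  utils::write.table(res, file.path(out_dir, sprintf("significant_%s.tsv", ct)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d up, %d down, %d not significant at p < 0.001",
                  ct, sum(res$status == "up"), sum(res$status == "down"),
                  sum(res$status == "not_significant")))
}

fs <- select_features(cm, n_components = 3, keep_fraction = 0.5)
utils::write.table(fs$report, file.path(out_dir, "feature_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(fs$retained, file.path(out_dir, "retained_genes.txt"))
message(sprintf("feature screen: %d of %d genes retained; PC1-3 explain %.1f%% of variance",
                length(fs$retained), length(cm$genes),
                100 * sum(fs$sdev[1:3]^2) / sum(fs$sdev^2)))
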