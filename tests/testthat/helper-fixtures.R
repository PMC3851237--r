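# Shared fixture builders.

study_timepoints <- c(1, 4, 10, 16, 22, 28)

# Noiseless cosine series sampled at the study's harvest times.
cosine_series <- function(mesor, amplitude, peak_h, period = 24,
                          times = study_timepoints) {
  mesor + amplitude * cos(2 * pi * (times - peak_h) / period)
}

# Small contrast matrix with symmetric effects so an all-zero profile sits
# exactly at the column means.
symmetric_contrast_fixture <- function() {
  l2 <- rbind(g_zero = rep(0, 5),
              g_up = c(1, 0.5, 2, 0.8, 1.5),
              g_dn = -c(1, 0.5, 2, 0.8, 1.5),
              g_up2 = c(2, 1, 0.4, 1.2, 0.6),
              g_dn2 = -c(2, 1, 0.4, 1.2, 0.6))
  colnames(l2) <- c("H_C", "T1_C", "T2_C", "T1_H", "T2_H")
  p <- matrix(0.5, nrow(l2), ncol(l2), dimnames = dimnames(l2))
  contrast_matrix(2^l2, p)
}

# A full synthetic input bundle on disk; returns the file paths.
synthetic_bundle <- function(dir, n_genes = 60, seed = 11) {
  gcp <- gen_contrast_profiles(n_genes, k_clusters = 5, noise_sd = 0.2,
                               seed = seed)
  geh <- gen_evidence_hypergraph(gcp$truth$gene_ids, edge_density = 0.05,
                                 seed = seed + 1)
  sets <- gen_annotation_sets(gcp$truth, coverage = 0.8, decoy_sets = 3,
                              seed = seed + 2)
  rp <- random_rhythm_params(gcp$truth$gene_ids[1:4], seed = seed + 3)
  ts <- gen_timeseries(rp, seed = seed + 4)
  paths <- list(contrasts = file.path(dir, "contrasts.tsv"),
                evidence = file.path(dir, "evidence.tsv"),
                gene_sets = file.path(dir, "sets.gmt"),
                timeseries = file.path(dir, "timeseries.tsv"))
  write_contrasts(gcp$matrix, paths$contrasts)
  write_evidence(geh$evidence, paths$evidence)
  write_gmt(sets, paths$gene_sets)
  write_timeseries(ts$series, paths$timeseries)
  paths$truth <- gcp$truth
  paths
}
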