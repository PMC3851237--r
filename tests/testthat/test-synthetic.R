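test_that("contrast simulation is deterministic and exact at zero noise", {
  one <- matrix(1, 1, 5)
  g1 <- gen_contrast_profiles(10, k_clusters = 1, effect_matrix = one,
                              noise_sd = 0, seed = 7)
  expect_true(all(g1$matrix$log2_ratio == 1))
  expect_true(all(g1$matrix$signed_fc == 2))
  expect_true(all(g1$matrix$p_value == 1e-300))

  g2 <- gen_contrast_profiles(10, k_clusters = 1, effect_matrix = one,
                              noise_sd = 0, seed = 7)
  expect_identical(g1$matrix, g2$matrix)

  a <- gen_contrast_profiles(50, seed = 7)
  b <- gen_contrast_profiles(50, seed = 7)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth$cluster_assignment, b$truth$cluster_assignment)

  expect_error(gen_contrast_profiles(0, seed = 1), "n_genes")
  expect_error(gen_contrast_profiles(3, k_clusters = 5, seed = 1),
               "k_clusters")
})

test_that("simulated p-values separate true effects from null genes", {
  eff <- rbind(c(1, 1, 1, 1, 1), c(0, 0, 0, 0, 0))
  g <- gen_contrast_profiles(200, k_clusters = 2, effect_matrix = eff,
                             noise_sd = 0.2, seed = 21)
  cl <- g$truth$cluster_assignment
  p_eff <- g$matrix$p_value[cl == 1, ]
  p_null <- g$matrix$p_value[cl == 2, ]
  expect_lt(stats::median(p_eff), 0.05)
  expect_gt(stats::median(p_null), 0.2) # near-uniform under the null
})

test_that("time-series simulation follows the planted cosine", {
  rp <- data.frame(gene = "G1", condition = "control", mesor = 1,
                   amplitude = 0.5, acrophase_deg = 60, noise_sd = 0)
  ts <- gen_timeseries(rp, n_replicates = 1, seed = 3)
  v4 <- ts$series$value[ts$series$time_h == 4]
  expect_equal(v4, 1.5, tolerance = 1e-12) # peak: 4 h x 15 deg/h = 60 deg

  flat <- data.frame(gene = "G1", condition = "control", mesor = 0.8,
                     amplitude = 0, acrophase_deg = 0, noise_sd = 0)
  tsf <- gen_timeseries(flat, n_replicates = 2, seed = 3)
  expect_true(all(tsf$series$value == 0.8))

  r1 <- gen_timeseries(rp, n_replicates = 3, seed = 5)
  r2 <- gen_timeseries(rp, n_replicates = 3, seed = 5)
  expect_identical(r1$series, r2$series)

  std <- gen_timeseries(rp, n_replicates = 1, seed = 3, standardize = TRUE)
  expect_equal(std$series$value[std$series$time_h == 1], 1)

  expect_error(gen_timeseries(rp, timepoints = numeric(), seed = 1),
               "non-empty")
})

test_that("evidence hypergraph generation honours density, hubs and seed", {
  genes <- sprintf("G%02d", 1:8)
  full <- gen_evidence_hypergraph(genes, n_categories = 1, edge_density = 1,
                                  weight_range = c(0.5, 0.5), seed = 2)
  expect_equal(nrow(full$evidence), choose(8, 2))
  expect_true(all(full$evidence$weight == 0.5))

  e1 <- gen_evidence_hypergraph(genes, edge_density = 0.3, seed = 4)
  e2 <- gen_evidence_hypergraph(genes, edge_density = 0.3, seed = 4)
  expect_identical(e1$evidence, e2$evidence)

  hub <- gen_evidence_hypergraph(sprintf("G%02d", 1:30), edge_density = 0.05,
                                 hub_genes = "G01", hub_boost = 5, seed = 8)
  deg <- table(c(hub$evidence$gene_a, hub$evidence$gene_b))
  expect_gt(deg[["G01"]], stats::median(deg))

  expect_error(gen_evidence_hypergraph(genes, hub_genes = "NOPE", seed = 1),
               "hub genes")
  expect_error(gen_evidence_hypergraph(genes, edge_density = 0, seed = 1),
               "edge_density")
})

test_that("annotation sets mirror planted clusters, with decoys", {
  g <- gen_contrast_profiles(40, k_clusters = 4, noise_sd = 0.1, seed = 13)
  full <- gen_annotation_sets(g$truth, coverage = 1, decoy_sets = 0,
                              seed = 14)
  clusters <- split(names(g$truth$cluster_assignment),
                    g$truth$cluster_assignment)
  expect_equal(length(full), 4)
  for (k in 1:4)
    expect_setequal(full[[paste0("planted_cluster_", k)]], clusters[[k]])

  part <- gen_annotation_sets(g$truth, coverage = 0.8, decoy_sets = 5,
                              seed = 14)
  expect_equal(length(part), 9)
  expect_true(all(part$planted_cluster_1 %in% clusters[[1]]))
  expect_identical(part, gen_annotation_sets(g$truth, coverage = 0.8,
                                             decoy_sets = 5, seed = 14))
})

test_that("generated tables round-trip through the writers and readers", {
  dir <- withr::local_tempdir()
  g <- gen_contrast_profiles(20, k_clusters = 2, noise_sd = 0.3, seed = 31)
  write_contrasts(g$matrix, file.path(dir, "cm.tsv"))
  cm2 <- read_contrasts(file.path(dir, "cm.tsv"))
  expect_equal(cm2$ratio, g$matrix$ratio)
  expect_equal(cm2$p_value, g$matrix$p_value)
  expect_equal(cm2$signed_fc, g$matrix$signed_fc)

  rp <- random_rhythm_params(c("A", "B"), seed = 32)
  ts <- gen_timeseries(rp, seed = 33)
  write_timeseries(ts$series, file.path(dir, "ts.tsv"))
  expect_equal(read_timeseries(file.path(dir, "ts.tsv")), ts$series)

  ev <- gen_evidence_hypergraph(c("A", "B", "C", "D"), edge_density = 0.9,
                                seed = 34)
  write_evidence(ev$evidence, file.path(dir, "ev.tsv"))
  expect_equal(read_evidence(file.path(dir, "ev.tsv")), ev$evidence)

  sets <- gen_annotation_sets(g$truth, coverage = 1, decoy_sets = 2,
                              seed = 35)
  write_gmt(sets, file.path(dir, "sets.gmt"))
  expect_equal(read_gmt(file.path(dir, "sets.gmt")), sets)

  write_truth(g$truth, file.path(dir, "truth.json"))
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr$cluster_assignment, g$truth$cluster_assignment)
  expect_equal(tr$contrast_effects, g$truth$contrast_effects)
  expect_equal(tr$seed, g$truth$seed)
})
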