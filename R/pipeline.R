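# End-to-end orchestration: feature screen -> hypergraph -> agglomeration ->
# topology indices -> consensus ranking -> closeness-scaled clustering ->
# enrichment, plus cosinor rhythmometry when a time-series table is supplied.

#' Assemble a pipeline configuration
#'
#' Collects the input paths and stage parameters of a full analysis run into
#' a validated flat list. All parameters have explicit defaults so a config
#' is auditable on its own.
#'
#' @param contrasts Path to the contrasts TSV (see [write_contrasts()]).
#' @param evidence Path to the interaction-evidence TSV (see
#'   [write_evidence()]).
#' @param gene_sets Path to a GMT file of gene sets.
#' @param out_dir Output directory; created by [run_all()] if missing.
#' @param timeseries Optional path to a time-series TSV; when NULL the
#'   rhythmometry stage is skipped.
#' @param alpha_ngs Significance threshold for sequencing contrasts.
#' @param alpha_qpcr Significance threshold for qRT-PCR comparisons.
#' @param n_components,keep_fraction Feature-screen parameters, see
#'   [select_features()].
#' @param top_k,agreement Consensus-ranking parameters, see
#'   [consensus_rank()].
#' @param k_clusters Number of clusters for [hcluster_profiles()].
#' @param closeness Closeness variant, see [weighted_closeness()].
#' @param linkage Clustering linkage, see [hcluster_profiles()].
#' @param ti_steps Walk length for [topological_importance()].
#' @param seed Optional integer seed recorded in the manifest (the pipeline
#'   itself is deterministic; the seed documents how synthetic inputs were
#'   produced).
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(contrasts, evidence, gene_sets, out_dir,
                            timeseries = NULL, alpha_ngs = 0.001,
                            alpha_qpcr = 0.05, n_components = 3,
                            keep_fraction = 0.5, top_k = 26, agreement = 4,
                            k_clusters = 5,
                            closeness = c("harmonic", "classic"),
                            linkage = c("ward", "average"), ti_steps = 2,
                            seed = NULL) {
  closeness <- match.arg(closeness)
  linkage <- match.arg(linkage)
  check_number(alpha_ngs, "alpha_ngs", 0, 1, open_min = TRUE, open_max = TRUE)
  check_number(alpha_qpcr, "alpha_qpcr", 0, 1, open_min = TRUE,
               open_max = TRUE)
  check_number(keep_fraction, "keep_fraction", 0, 1, open_min = TRUE)
  cfg <- list(contrasts = contrasts, evidence = evidence,
              gene_sets = gene_sets, timeseries = timeseries,
              out_dir = out_dir, alpha_ngs = alpha_ngs,
              alpha_qpcr = alpha_qpcr,
              n_components = check_count(n_components, "n_components"),
              keep_fraction = keep_fraction,
              top_k = check_count(top_k, "top_k"),
              agreement = check_count(agreement, "agreement"),
              k_clusters = check_count(k_clusters, "k_clusters"),
              closeness = closeness, linkage = linkage,
              ti_steps = check_count(ti_steps, "ti_steps"),
              seed = if (!is.null(seed))
                check_count(seed, "seed", min = -.Machine$integer.max))
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: the feature screen on the contrast table; hypergraph
#' assembly from the evidence table restricted to retained genes;
#' agglomeration into a weighted graph; the five topology indices and global
#' network statistics; consensus ranking of central genes; closeness-scaled
#' hierarchical clustering; gene-set enrichment; and, when a time-series
#' table is configured, cosinor rhythmometry with polarogram export. Every
#' intermediate artifact is written under `out_dir`, and a manifest (input
#' hashes, parameters, output hashes, package version — no timestamps, so
#' reruns are hash-stable) is written as `manifest.json`. A stage failure
#' halts the run with the failing stage named; artifacts of completed stages
#' are retained.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_all <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must be a pipeline_config")
  inputs <- c(contrasts = config$contrasts, evidence = config$evidence,
              gene_sets = config$gene_sets)
  if (!is.null(config$timeseries))
    inputs <- c(inputs, timeseries = config$timeseries)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0)
    stopf("input file(s) not found: %s", paste(missing, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  outputs <- character()

  pipeline_log("read", sprintf("loading %d input table(s)", length(inputs)))
  cm <- run_stage("read", read_contrasts(config$contrasts))
  evidence <- run_stage("read", read_evidence(config$evidence))
  sets <- run_stage("read", read_gmt(config$gene_sets))

  pipeline_log("features", sprintf("screening %d genes", length(cm$genes)))
  feats <- run_stage("features",
                     select_features(cm, config$n_components,
                                     config$keep_fraction))
  write_tsv(feats$report, out("features_report.tsv"))
  writeLines(feats$retained, out("retained_genes.txt"))
  outputs <- c(outputs, "features_report.tsv", "retained_genes.txt")

  pipeline_log("network", sprintf("%d genes retained; building hypergraph",
                                  length(feats$retained)))
  keep <- evidence$gene_a %in% feats$retained &
    evidence$gene_b %in% feats$retained
  h <- run_stage("network",
                 build_hypergraph(evidence[keep, , drop = FALSE],
                                  node_weights = cm, unknown_genes = "drop"))
  g <- run_stage("network", agglomerate(h))
  write_weighted_graph(g, out("weighted_graph.tsv"))
  outputs <- c(outputs, "weighted_graph.tsv")

  pipeline_log("topology", sprintf("indices over %d nodes, %d edges",
                                   length(g$nodes), nrow(g$edges)))
  tt <- run_stage("topology",
                  topology_table(g, closeness = config$closeness,
                                 ti_steps = config$ti_steps))
  write_tsv(as.data.frame(tt), out("topology.tsv"))
  gs <- run_stage("topology", global_stats(g))
  jsonlite::write_json(gs, out("global_stats.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs <- c(outputs, "topology.tsv", "global_stats.json")

  pipeline_log("consensus", sprintf("top %d by closeness, agreement %d of 5",
                                    config$top_k, config$agreement))
  central <- run_stage("consensus",
                       consensus_rank(tt, config$top_k, config$agreement))
  write_tsv(central, out("central_genes.tsv"))
  outputs <- c(outputs, "central_genes.tsv")

  pipeline_log("clusters", sprintf("closeness-scaled clustering, k = %d",
                                   config$k_clusters))
  cl_values <- stats::setNames(tt$closeness, tt$gene)
  cm_graph <- run_stage("clusters", {
    keep_genes <- cm$genes %in% g$nodes
    contrast_matrix(cm$ratio[keep_genes, , drop = FALSE],
                    cm$p_value[keep_genes, , drop = FALSE])
  })
  profiles <- run_stage("clusters", scale_by_closeness(cm_graph, cl_values))
  clusters <- run_stage("clusters",
                        hcluster_profiles(profiles, k = config$k_clusters,
                                          linkage = config$linkage))
  assign_df <- data.frame(gene = names(clusters$assignment),
                          cluster = as.integer(clusters$assignment),
                          stringsAsFactors = FALSE)
  write_tsv(assign_df, out("clusters.tsv"))
  phy <- ape::as.phylo(clusters$tree)
  ape::write.tree(phy, out("dendrogram.nwk"))
  outputs <- c(outputs, "clusters.tsv", "dendrogram.nwk")

  pipeline_log("enrich", sprintf("%d gene sets against %d-gene universe",
                                 length(sets), length(g$nodes)))
  enr <- run_stage("enrich",
                   enrich_sets(clusters, sets, universe = g$nodes,
                               alpha = config$alpha_qpcr))
  write_tsv(enr, out("enrichment.tsv"))
  outputs <- c(outputs, "enrichment.tsv")

  if (!is.null(config$timeseries)) {
    pipeline_log("rhythms", "cosinor rhythmometry")
    series <- run_stage("rhythms", read_timeseries(config$timeseries))
    rt <- run_stage("rhythms", rhythm_table(series))
    write_tsv(rt, out("rhythms.tsv"))
    utils::write.csv(format_tsv_cols(polarogram_table(rt)),
                     out("polarogram.csv"), row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, "rhythms.tsv", "polarogram.csv")
  } else {
    pipeline_log("rhythms", "no time-series table configured; stage skipped")
  }

  manifest <- list(
    package = "circnet",
    version = as.character(utils::packageVersion("circnet")),
    parameters = unclass(config)[setdiff(names(config),
                                         c("contrasts", "evidence",
                                           "gene_sets", "timeseries",
                                           "out_dir"))],
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                     names(inputs))),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  pipeline_log("done", sprintf("%d artifacts in %s", length(outputs) + 1L,
                               config$out_dir))
  invisible(manifest)
}
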