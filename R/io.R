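# Readers and writers for the plain-text table dialects the pipeline
# exchanges. Numeric columns are written with 17 significant digits so a
# write/read round trip reproduces the in-memory objects exactly.

#' Write / read a contrast matrix as TSV
#'
#' Columns are `gene`, then `ratio_<contrast>`, `fc_<contrast>`,
#' `p_<contrast>` for each of the five contrasts. The fold-change columns are
#' derived from the ratios; the reader recomputes them, so the ratio columns
#' are authoritative.
#'
#' @param cm A [contrast_matrix()].
#' @param path File path.
#' @return `write_contrasts` returns `path` invisibly; `read_contrasts`
#'   returns a [contrast_matrix()].
#' @export
write_contrasts <- function(cm, path) {
  if (!inherits(cm, "contrast_matrix")) stopf("'cm' must be a contrast_matrix")
  df <- data.frame(gene = cm$genes, stringsAsFactors = FALSE)
  for (ct in cm$contrasts) {
    df[[paste0("ratio_", ct)]] <- unname(cm$ratio[, ct])
    df[[paste0("fc_", ct)]] <- unname(cm$signed_fc[, ct])
    df[[paste0("p_", ct)]] <- unname(cm$p_value[, ct])
  }
  write_tsv(df, path)
}

#' @rdname write_contrasts
#' @export
read_contrasts <- function(path) {
  df <- read_tsv(path)
  ratio_cols <- grep("^ratio_", names(df), value = TRUE)
  contrasts <- sub("^ratio_", "", ratio_cols)
  ratio <- as.matrix(df[, paste0("ratio_", contrasts), drop = FALSE])
  p <- as.matrix(df[, paste0("p_", contrasts), drop = FALSE])
  dimnames(ratio) <- dimnames(p) <- list(df$gene, contrasts)
  contrast_matrix(ratio, p)
}

#' Write / read a time-series table as TSV
#'
#' Columns: `gene`, `condition`, `replicate`, `time_h`, `value`.
#'
#' @param series Data frame in the [gen_timeseries()] dialect.
#' @param path File path.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   the data frame.
#' @export
write_timeseries <- function(series, path) {
  need <- c("gene", "condition", "replicate", "time_h", "value")
  if (!all(need %in% names(series)))
    stopf("'series' must have columns %s", paste(need, collapse = ", "))
  write_tsv(series[, need], path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) read_tsv(path)

#' Write / read an evidence table as TSV
#'
#' Columns: `gene_a`, `gene_b`, `category`, `weight`, `sign`.
#'
#' @param evidence Data frame in the [gen_evidence_hypergraph()] dialect.
#' @param path File path.
#' @return `write_evidence` returns `path` invisibly; `read_evidence` the
#'   data frame.
#' @export
write_evidence <- function(evidence, path) {
  need <- c("gene_a", "gene_b", "category", "weight", "sign")
  if (!all(need %in% names(evidence)))
    stopf("'evidence' must have columns %s", paste(need, collapse = ", "))
  write_tsv(evidence[, need], path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) read_tsv(path)

#' Write a weighted graph as a TSV edge list
#'
#' Node/edge attribute table loadable by common network viewers: one row per
#' edge with `from`, `to`, `weight`, `n_evidence`, `sign`. Isolated nodes are
#' appended to a companion `<path>.nodes` file listing all node names.
#'
#' @param g A [weighted_graph()].
#' @param path File path for the edge list.
#' @return `path`, invisibly.
#' @export
write_weighted_graph <- function(g, path) {
  if (!inherits(g, "weighted_graph")) stopf("'g' must be a weighted_graph")
  write_tsv(g$edges[, c("from", "to", "weight", "n_evidence", "sign")], path)
  writeLines(g$nodes, paste0(path, ".nodes"))
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' GMT is one set per line: name, description, then member genes, all
#' tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param description Description field written for every set.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` a named list of
#'   character vectors.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  if (is.null(names(sets))) stopf("'sets' must be a named list")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write / read a synthetic ground-truth record as JSON
#'
#' @param truth A [synthetic_truth()].
#' @param path File path.
#' @return `write_truth` returns `path` invisibly; `read_truth` a
#'   [synthetic_truth()].
#' @export
write_truth <- function(truth, path) {
  if (!inherits(truth, "synthetic_truth"))
    stopf("'truth' must be a synthetic_truth")
  x <- unclass(truth)
  if (!is.null(x$cluster_assignment))
    x$cluster_assignment <- as.list(x$cluster_assignment)
  if (!is.null(x$contrast_effects)) {
    x$contrast_effect_rows <- rownames(x$contrast_effects)
    x$contrast_effect_cols <- colnames(x$contrast_effects)
    x$contrast_effects <- unname(apply(x$contrast_effects, 1, c,
                                       simplify = FALSE))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ca <- NULL
  if (!is.null(x$cluster_assignment))
    ca <- stats::setNames(as.integer(unlist(x$cluster_assignment)),
                          names(x$cluster_assignment))
  ce <- NULL
  if (!is.null(x$contrast_effects)) {
    ce <- if (is.list(x$contrast_effects))
      do.call(rbind, x$contrast_effects) else as.matrix(x$contrast_effects)
    dimnames(ce) <- list(x$contrast_effect_rows, x$contrast_effect_cols)
  }
  synthetic_truth(x$gene_ids, cluster_assignment = ca,
                  hub_genes = x$hub_genes,
                  rhythm_params = if (!is.null(x$rhythm_params))
                    as.data.frame(x$rhythm_params) else NULL,
                  contrast_effects = ce, seed = x$seed)
}
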