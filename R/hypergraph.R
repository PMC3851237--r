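#' Assemble an evidence hypergraph from interaction-evidence rows
#'
#' Builds a signed, weighted multigraph over genes in which parallel edges
#' record independent interaction evidences (one per evidence category, each
#' with a reliability weight in (0, 1] and a sign). Two genes are connected
#' whenever at least one evidence of any category links them. Gene pair order
#' is canonicalized, self-edges are dropped with a warning, and rows that
#' duplicate the same (pair, category, weight) are deduplicated with a
#' message.
#'
#' @param evidence Data frame with columns `gene_a`, `gene_b`, `category`,
#'   `weight` and optionally `sign` (defaults to +1).
#' @param node_weights Optional per-gene node weights carrying the fold-change
#'   profile: a [contrast_matrix()] (its signed fold changes are used) or a
#'   numeric matrix with gene row names, or NULL.
#' @param unknown_genes What to do with evidence genes absent from
#'   `node_weights`: `"add"` keeps them with zero node weight, `"drop"`
#'   removes their edges. Ignored when `node_weights` is NULL.
#' @return An object of class `evidence_hypergraph`: a list with `nodes`,
#'   `edges` (gene_a, gene_b, category, weight, sign) and `node_weights`
#'   (matrix or NULL).
#' @export
build_hypergraph <- function(evidence, node_weights = NULL,
                             unknown_genes = c("add", "drop")) {
  unknown_genes <- match.arg(unknown_genes)
  need <- c("gene_a", "gene_b", "category", "weight")
  if (!all(need %in% names(evidence)))
    stopf("'evidence' must have columns %s", paste(need, collapse = ", "))
  ev <- evidence
  if (is.null(ev$sign)) ev$sign <- 1L
  if (any(!is.finite(ev$weight)) || any(ev$weight <= 0) || any(ev$weight > 1))
    stopf("evidence weights must lie in (0, 1]")
  self <- ev$gene_a == ev$gene_b
  if (any(self)) {
    warnf("dropping %d self-edge row(s)", sum(self))
    ev <- ev[!self, , drop = FALSE]
  }
  swap <- ev$gene_a > ev$gene_b
  tmp <- ev$gene_a[swap]
  ev$gene_a[swap] <- ev$gene_b[swap]
  ev$gene_b[swap] <- tmp
  dup <- duplicated(ev[, c("gene_a", "gene_b", "category", "weight")])
  if (any(dup)) {
    message(sprintf("deduplicated %d repeated evidence row(s)", sum(dup)))
    ev <- ev[!dup, , drop = FALSE]
  }
  ev <- ev[order(ev$gene_a, ev$gene_b, ev$category, ev$weight), , drop = FALSE]
  rownames(ev) <- NULL
  nodes <- sort(unique(c(ev$gene_a, ev$gene_b)))
  nw <- NULL
  if (!is.null(node_weights)) {
    nw <- if (inherits(node_weights, "contrast_matrix"))
      node_weights$signed_fc else as.matrix(node_weights)
    if (is.null(rownames(nw))) stopf("'node_weights' must have gene row names")
    unknown <- setdiff(nodes, rownames(nw))
    if (length(unknown) > 0) {
      if (unknown_genes == "drop") {
        keep <- !(ev$gene_a %in% unknown | ev$gene_b %in% unknown)
        ev <- ev[keep, , drop = FALSE]
        nodes <- sort(unique(c(ev$gene_a, ev$gene_b)))
      } else {
        pad <- matrix(0, length(unknown), ncol(nw),
                      dimnames = list(unknown, colnames(nw)))
        nw <- rbind(nw, pad)
      }
    }
    nw <- nw[intersect(rownames(nw), nodes), , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = ev, node_weights = nw),
            class = "evidence_hypergraph")
}

#' @export
print.evidence_hypergraph <- function(x, ...) {
  cat(sprintf("evidence_hypergraph: %d nodes, %d evidence edges, %d categories\n",
              length(x$nodes), nrow(x$edges),
              length(unique(x$edges$category))))
  invisible(x)
}

#' Majority sign per connected gene pair
#'
#' Summarizes the evidence signs of each connected pair into a net sign:
#' +1 when positive evidences outnumber negative ones, -1 for the converse,
#' and 0 on a tie (unsigned). The sign is edge metadata only; it does not
#' enter the agglomerated weight.
#'
#' @param h An [build_hypergraph()] result.
#' @return Data frame with columns `gene_a`, `gene_b`, `sign`.
#' @export
edge_sign_summary <- function(h) {
  if (!inherits(h, "evidence_hypergraph"))
    stopf("'h' must be an evidence_hypergraph")
  key <- paste(h$edges$gene_a, h$edges$gene_b, sep = "\r")
  s <- tapply(h$edges$sign, key, function(v) sign(sum(v)))
  parts <- strsplit(names(s), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                    gene_b = vapply(parts, `[`, "", 2),
                    sign = as.integer(s), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Agglomerate an evidence hypergraph into a weighted simple graph
#'
#' Collapses the parallel evidence edges between every connected gene pair
#' into a single undirected edge whose weight is
#' `W_AB = (exp(n) / n) * sum(W_i) = exp(n) * mean(W_i)`, where the `W_i` are
#' the `n` evidence reliability weights of the pair. The exponential factor
#' makes the agglomerated weight grow strictly with the number of supporting
#' evidences at fixed mean reliability, so multiply-evidenced pairs dominate
#' the downstream shortest-path metrics.
#'
#' @param h An [build_hypergraph()] result.
#' @return An object of class `weighted_graph`: a list with `nodes`, `edges`
#'   (from, to, weight, n_evidence, sign) and `node_weights`.
#' @export
agglomerate <- function(h) {
  if (!inherits(h, "evidence_hypergraph"))
    stopf("'h' must be an evidence_hypergraph")
  ev <- h$edges
  if (nrow(ev) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), n_evidence = integer(),
                        sign = integer(), stringsAsFactors = FALSE)
    return(weighted_graph(h$nodes, edges, h$node_weights))
  }
  key <- paste(ev$gene_a, ev$gene_b, sep = "\r")
  n <- tapply(ev$weight, key, length)
  w <- exp(n) * tapply(ev$weight, key, mean)
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      weight = as.numeric(w),
                      n_evidence = as.integer(n),
                      stringsAsFactors = FALSE)
  signs <- edge_sign_summary(h)
  edges <- merge(edges, signs, by.x = c("from", "to"),
                 by.y = c("gene_a", "gene_b"), sort = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  weighted_graph(h$nodes, edges, h$node_weights)
}

#' Construct a weighted simple graph
#'
#' Low-level constructor for the agglomerated-graph container; [agglomerate()]
#' is the usual way to obtain one.
#'
#' @param nodes Character vector of node (gene) identifiers.
#' @param edges Data frame with columns `from`, `to`, `weight` and optionally
#'   `n_evidence`, `sign`.
#' @param node_weights Optional matrix of per-node weights (gene row names).
#' @return An object of class `weighted_graph`.
#' @export
weighted_graph <- function(nodes, edges, node_weights = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stopf("node identifiers must be unique")
  if (!all(c("from", "to", "weight") %in% names(edges)))
    stopf("'edges' must have columns from, to, weight")
  if (!all(c(edges$from, edges$to) %in% nodes))
    stopf("edge endpoints must be listed in 'nodes'")
  if (any(edges$from == edges$to)) stopf("self-edges are not allowed")
  if (nrow(edges) > 0 && (any(!is.finite(edges$weight)) ||
                          any(edges$weight <= 0)))
    stopf("edge weights must be positive and finite")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stopf("duplicate edges in a simple graph")
  if (is.null(edges$n_evidence)) edges$n_evidence <- rep(1L, nrow(edges))
  if (is.null(edges$sign)) edges$sign <- rep(1L, nrow(edges))
  structure(list(nodes = nodes, edges = edges, node_weights = node_weights),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a circnet graph to an igraph object
#'
#' @param g A [weighted_graph()] or [build_hypergraph()] result.
#' @return An undirected `igraph` graph; evidence hypergraphs keep parallel
#'   edges with `category`, `weight` and `sign` attributes, weighted graphs
#'   carry `weight`, `n_evidence` and `sign`.
#' @export
as_igraph <- function(g) {
  if (inherits(g, "weighted_graph")) {
    igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                  vertices = data.frame(name = g$nodes))
  } else if (inherits(g, "evidence_hypergraph")) {
    igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                  vertices = data.frame(name = g$nodes))
  } else {
    stopf("'g' must be a weighted_graph or evidence_hypergraph")
  }
}
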