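# Weighted topology indices. Shortest paths use edge lengths 1/W, so highly
# reliable (heavily agglomerated) connections are short and central genes sit
# on reliable paths.

graph_lengths <- function(g) {
  if (!inherits(g, "weighted_graph")) stopf("'g' must be a weighted_graph")
  if (nrow(g$edges) > 0 && (any(!is.finite(g$edges$weight)) ||
                            any(g$edges$weight <= 0)))
    stopf("edge weights must be positive and finite")
  1 / g$edges$weight
}

#' Weighted closeness centrality
#'
#' Distances are shortest paths under edge lengths `1/W`, so the distance
#' between two genes is small when they are linked by reliable, multiply
#' evidenced interactions. Two aggregations are available: `"harmonic"`
#' (default) sums `1/d(u, v)` over all other nodes and handles disconnected
#' graphs gracefully (unreachable nodes contribute 0); `"classic"` is
#' `(n_c - 1) / sum(d(u, v))` within each connected component of size `n_c`.
#' Higher values mean more central.
#'
#' @param g A [weighted_graph()].
#' @param mode `"harmonic"` or `"classic"`.
#' @return Named numeric vector over `g$nodes`.
#' @export
weighted_closeness <- function(g, mode = c("harmonic", "classic")) {
  mode <- match.arg(mode)
  len <- graph_lengths(g)
  ig <- as_igraph(g)
  n <- length(g$nodes)
  if (n == 1) return(stats::setNames(0, g$nodes))
  d <- igraph::distances(ig, weights = len)
  comp <- igraph::components(ig)
  if (comp$no > 1)
    warnf("graph is disconnected; closeness computed within components")
  diag(d) <- Inf
  out <- if (mode == "harmonic") {
    rowSums(1 / d)
  } else {
    vapply(seq_len(n), function(u) {
      members <- which(comp$membership == comp$membership[u])
      others <- setdiff(members, u)
      if (length(others) == 0) return(0)
      length(others) / sum(d[u, others])
    }, numeric(1))
  }
  stats::setNames(as.numeric(out), g$nodes)
}

#' Weighted betweenness centrality
#'
#' Shortest-path betweenness under edge lengths `1/W`, normalized by
#' `(n - 1) * (n - 2) / 2`, the number of node pairs a vertex could possibly
#' separate, so values lie in `[0, 1]`.
#'
#' @param g A [weighted_graph()].
#' @return Named numeric vector over `g$nodes`.
#' @export
weighted_betweenness <- function(g) {
  len <- graph_lengths(g)
  ig <- as_igraph(g)
  n <- length(g$nodes)
  if (n < 3) return(stats::setNames(numeric(n), g$nodes))
  b <- igraph::betweenness(ig, directed = FALSE, weights = len)
  stats::setNames(as.numeric(b) / ((n - 1) * (n - 2) / 2), g$nodes)
}

#' Normalized weighted degree (strength)
#'
#' The strength of a gene is the sum of its incident agglomerated edge
#' weights, divided by a normalizer. The default normalizer is the mean
#' strength over all nodes, which makes the index scale-free: multiplying all
#' edge weights by a constant leaves it unchanged.
#'
#' @param g A [weighted_graph()].
#' @param normalizer `"mean"` (divide by mean strength), `"none"`, or a
#'   positive number.
#' @return Named numeric vector over `g$nodes`.
#' @export
degree_strength <- function(g, normalizer = "mean") {
  graph_lengths(g)  # weight validation
  ig <- as_igraph(g)
  s <- igraph::strength(ig, weights = igraph::E(ig)$weight)
  div <- if (identical(normalizer, "mean")) {
    m <- mean(s)
    if (m > 0) m else 1
  } else if (identical(normalizer, "none")) {
    1
  } else if (is.numeric(normalizer) && length(normalizer) == 1 &&
             normalizer > 0) {
    normalizer
  } else {
    stopf("'normalizer' must be \"mean\", \"none\" or a positive number")
  }
  stats::setNames(as.numeric(s) / div, g$nodes)
}

#' Local clustering coefficient
#'
#' Unweighted local transitivity: the fraction of a gene's neighbour pairs
#' that are themselves connected (`triangles / choose(k, 2)`); genes with
#' fewer than two neighbours score 0.
#'
#' @param g A [weighted_graph()].
#' @return Named numeric vector in `[0, 1]` over `g$nodes`.
#' @export
local_clustering <- function(g) {
  if (!inherits(g, "weighted_graph")) stopf("'g' must be a weighted_graph")
  ig <- as_igraph(g)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  stats::setNames(as.numeric(cc), g$nodes)
}

#' Topological importance index
#'
#' Indirect-effect centrality over bounded-length paths, in the tradition of
#' ecological-network importance indices. The one-step effect of gene `i` on
#' an adjacent gene `j` is `1/deg(j)` (the receiver divides incoming
#' influence equally among its neighbours); the m-step effect is the matrix
#' power of the one-step effect matrix, summing over all walks. The index of
#' gene `i` is the total effect it spreads over 1..`steps` steps, averaged
#' per step:
#' `TI_i = (1/steps) * sum_m sum_j (M^m)[i, j]` with `M[i, j] = A[i, j] / deg(j)`.
#'
#' @param g A [weighted_graph()] (the index uses the unweighted topology).
#' @param steps Maximum walk length (>= 1, default 2).
#' @return Named numeric vector over `g$nodes`.
#' @export
topological_importance <- function(g, steps = 2) {
  if (!inherits(g, "weighted_graph")) stopf("'g' must be a weighted_graph")
  steps <- check_count(steps, "steps", 1L)
  ig <- as_igraph(g)
  a <- igraph::as_adjacency_matrix(ig, sparse = FALSE)
  a[a > 0] <- 1
  deg <- colSums(a)
  m <- sweep(a, 2, pmax(deg, 1), "/")
  acc <- numeric(nrow(a))
  pm <- diag(nrow(a))
  for (s in seq_len(steps)) {
    pm <- pm %*% m
    acc <- acc + rowSums(pm)
  }
  stats::setNames(acc / steps, g$nodes)
}

#' Table of the five topology indices with per-index ranks
#'
#' Computes normalized weighted degree, weighted betweenness, weighted
#' closeness, local clustering coefficient and topological importance for
#' every gene, plus a deterministic rank per index (1 = most central; ties
#' broken by higher closeness, then lexicographic gene id).
#'
#' @param g A [weighted_graph()].
#' @param closeness Closeness variant, see [weighted_closeness()].
#' @param ti_steps Walk length for [topological_importance()].
#' @param degree_normalizer Passed to [degree_strength()].
#' @return A data frame of class `topology_table` with columns `gene`, the
#'   five indices, and `rank_<index>` columns.
#' @export
topology_table <- function(g, closeness = c("harmonic", "classic"),
                           ti_steps = 2, degree_normalizer = "mean") {
  closeness <- match.arg(closeness)
  cl <- weighted_closeness(g, closeness)
  tt <- data.frame(gene = g$nodes,
                   degree_strength = as.numeric(degree_strength(g, degree_normalizer)),
                   betweenness = as.numeric(weighted_betweenness(g)),
                   closeness = as.numeric(cl),
                   clustering_coefficient = as.numeric(local_clustering(g)),
                   topological_importance = as.numeric(topological_importance(g, ti_steps)),
                   stringsAsFactors = FALSE)
  for (idx in c("degree_strength", "betweenness", "closeness",
                "clustering_coefficient", "topological_importance")) {
    tt[[paste0("rank_", idx)]] <-
      rank_stable(tt[[idx]], tt$closeness, tt$gene)
  }
  class(tt) <- c("topology_table", "data.frame")
  tt
}

#' Global network statistics
#'
#' Hop-count (unweighted) summary of a graph: mean local clustering
#' coefficient, number of connected components, diameter and radius (largest
#' and smallest eccentricity over reachable pairs), degree centralization
#' (star-normalized), the number of ordered reachable node pairs
#' (`N * (N - 1)` when connected), characteristic path length (mean hop
#' distance over reachable ordered pairs), average neighbour count `2E/N`,
#' density `2E / (N * (N - 1))` and degree heterogeneity (population
#' coefficient of variation of the degree sequence).
#'
#' @param g A [weighted_graph()].
#' @return A list with elements `clustering_coefficient`,
#'   `connected_components`, `diameter`, `radius`, `centralization`,
#'   `shortest_paths_count`, `characteristic_path_length`, `avg_neighbors`,
#'   `density`, `heterogeneity`, `n_nodes`, `n_edges`.
#' @export
global_stats <- function(g) {
  if (!inherits(g, "weighted_graph")) stopf("'g' must be a weighted_graph")
  n <- length(g$nodes)
  if (n == 0) stopf("the graph is empty")
  ig <- as_igraph(g)
  ne <- nrow(g$edges)
  deg <- as.numeric(igraph::degree(ig))
  d <- igraph::distances(ig, weights = NA)  # hop counts, not edge weights
  off <- d[row(d) != col(d)]
  reach <- off[is.finite(off)]
  ecc <- apply(d, 1, function(r) {
    r <- r[is.finite(r) & r > 0]
    if (length(r) == 0) 0 else max(r)
  })
  mean_deg <- mean(deg)
  het <- if (mean_deg > 0)
    sqrt(mean(deg^2) - mean_deg^2) / mean_deg else 0
  centralization <- if (n > 2)
    sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0
  list(clustering_coefficient = mean(local_clustering(g)),
       connected_components = igraph::components(ig)$no,
       diameter = if (length(reach) > 0) max(reach) else 0,
       radius = if (length(reach) > 0) min(ecc[ecc > 0]) else 0,
       centralization = centralization,
       shortest_paths_count = length(reach),
       characteristic_path_length = if (length(reach) > 0) mean(reach) else 0,
       avg_neighbors = 2 * ne / n,
       density = if (n > 1) 2 * ne / (n * (n - 1)) else 0,
       heterogeneity = het,
       n_nodes = n, n_edges = ne)
}

#' Consensus ranking of central genes across the five indices
#'
#' Restricts attention to the `top_k` genes by weighted closeness, then calls
#' a gene central when it appears in the top `top_k` of at least `agreement`
#' of the five index rankings. Results are ordered by closeness rank, ties by
#' gene id.
#'
#' @param tt A [topology_table()].
#' @param top_k Size of each index's top list (default 26); clamped to the
#'   number of genes with a warning.
#' @param agreement Minimum number of indices (out of 5) that must rank a
#'   gene in their top `top_k` (default 4).
#' @return Data frame with columns `gene`, `closeness_rank`, `n_indices`
#'   (how many index top lists contain the gene) and `central` (logical).
#' @export
consensus_rank <- function(tt, top_k = 26, agreement = 4) {
  if (!inherits(tt, "topology_table")) stopf("'tt' must be a topology_table")
  top_k <- check_count(top_k, "top_k", 1L)
  agreement <- check_count(agreement, "agreement", 1L)
  if (agreement > 5) stopf("'agreement' cannot exceed the 5 indices")
  n <- nrow(tt)
  if (top_k > n) {
    warnf("'top_k' (%d) exceeds the number of genes (%d); clamped", top_k, n)
    top_k <- n
  }
  rank_cols <- grep("^rank_", names(tt), value = TRUE)
  in_top <- sapply(rank_cols, function(cn) tt[[cn]] <= top_k)
  if (is.null(dim(in_top))) in_top <- matrix(in_top, nrow = n)
  n_indices <- rowSums(in_top)
  base <- tt$rank_closeness <= top_k
  out <- data.frame(gene = tt$gene[base],
                    closeness_rank = tt$rank_closeness[base],
                    n_indices = n_indices[base],
                    stringsAsFactors = FALSE)
  out$central <- out$n_indices >= agreement
  out <- out[order(out$closeness_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
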