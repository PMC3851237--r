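# Brute-force oracles, written independently of the package internals (and
# of igraph): Floyd-Warshall distances, simple-path enumeration for
# betweenness, triangle counting, and recursive walk sums for the
# topological-importance index. All operate on a plain weight matrix.

# Symmetric weight matrix of a weighted_graph (0 = no edge).
wg_matrix <- function(g) {
  n <- length(g$nodes)
  w <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$from[i]; b <- g$edges$to[i]
    w[a, b] <- w[b, a] <- g$edges$weight[i]
  }
  w
}

oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_harmonic_closeness <- function(w) {
  d <- oracle_distances(w)
  diag(d) <- Inf
  rowSums(1 / d)
}

oracle_classic_closeness <- function(w) {
  d <- oracle_distances(w)
  vapply(seq_len(nrow(w)), function(u) {
    du <- d[u, -u]
    du <- du[is.finite(du)]
    if (length(du) == 0) 0 else length(du) / sum(du)
  }, numeric(1))
}

# All simple paths from s to t, as lists of vertex index vectors.
all_simple_paths_idx <- function(adj, s, t) {
  out <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (u in which(adj[v, ] > 0)) if (!(u %in% path)) recurse(c(path, u))
  }
  recurse(s)
  out
}

# Shortest-path betweenness by exhaustive path enumeration; lengths are sums
# of inverse weights. Edge weights in tests are dyadic rationals, so length
# comparisons are exact in floating point.
oracle_betweenness <- function(w) {
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- all_simple_paths_idx(w, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, function(p) {
        sum(vapply(seq_len(length(p) - 1),
                   function(i) 1 / w[p[i], p[i + 1]], numeric(1)))
      }, numeric(1))
      dmin <- min(lens)
      shortest <- paths[lens == dmin]
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        bc[interior] <- bc[interior] + 1 / length(shortest)
      }
    }
  }
  if (n < 3) return(bc)
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_local_clustering <- function(w) {
  adj <- w > 0
  vapply(seq_len(nrow(w)), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1))
      for (j in seq(i + 1, k))
        if (adj[nb[i], nb[j]]) tri <- tri + 1
    tri / (k * (k - 1) / 2)
  }, numeric(1))
}

# Walk-sum oracle for the topological-importance index: the total effect a
# node spreads over walks of exactly m hops, each arrival attenuated by the
# receiving node's degree, recursively; averaged over m = 1..steps.
oracle_topological_importance <- function(w, steps = 2) {
  adj <- w > 0
  deg <- rowSums(adj)
  spread <- function(v, m) {
    nb <- which(adj[v, ])
    if (length(nb) == 0) return(0)
    total <- 0
    for (u in nb) {
      eff <- 1 / deg[u]
      total <- total + if (m == 1) eff else eff * spread(u, m - 1)
    }
    total
  }
  vapply(seq_len(nrow(w)), function(v)
    mean(vapply(seq_len(steps), function(m) spread(v, m), numeric(1))),
    numeric(1))
}

# Random connected graph as a weighted_graph: random spanning tree plus
# Bernoulli extra edges; dyadic weights keep inverse-length sums exact.
random_connected_wg <- function(n, extra_prob = 0.25,
                                weights = c(0.25, 0.5, 1, 2)) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  edge <- logical(nrow(pairs))
  for (v in 2:n) { # attach each node to a random earlier one
    u <- sample.int(v - 1, 1)
    edge[pairs[, 1] == u & pairs[, 2] == v] <- TRUE
  }
  edge <- edge | stats::runif(nrow(pairs)) < extra_prob
  idx <- which(edge)
  weighted_graph(nodes, data.frame(
    from = nodes[pairs[idx, 1]], to = nodes[pairs[idx, 2]],
    weight = sample(weights, length(idx), replace = TRUE),
    stringsAsFactors = FALSE))
}

# Exact hypergeometric upper tail from binomial coefficients, independent of
# stats::phyper.
oracle_hyper_p <- function(overlap, set_size, cluster_size, universe) {
  ks <- overlap:min(set_size, cluster_size)
  sum(choose(set_size, ks) * choose(universe - set_size, cluster_size - ks)) /
    choose(universe, cluster_size)
}
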