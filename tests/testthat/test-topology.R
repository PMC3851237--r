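triangle_wg <- function(w = 1) {
  weighted_graph(c("A", "B", "C"),
                 data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                            weight = w, stringsAsFactors = FALSE))
}

path_wg <- function() {
  weighted_graph(c("A", "B", "C"),
                 data.frame(from = c("A", "B"), to = c("B", "C"), weight = 1,
                            stringsAsFactors = FALSE))
}

star_wg <- function(k = 5, w = 1) {
  leaves <- paste0("L", seq_len(k))
  weighted_graph(c("H", leaves),
                 data.frame(from = "H", to = leaves, weight = w,
                            stringsAsFactors = FALSE))
}

test_that("weighted closeness matches hand-computed distances", {
  tri <- triangle_wg()
  expect_equal(unname(weighted_closeness(tri, "harmonic")), rep(2, 3))
  expect_equal(unname(weighted_closeness(tri, "classic")), rep(1, 3))

  p <- path_wg()
  h <- weighted_closeness(p, "harmonic")
  expect_equal(unname(h[c("A", "B", "C")]), c(1.5, 2, 1.5))

  # shortest paths use inverse weights: a heavy 2-hop route beats a weak edge
  g <- weighted_graph(c("A", "B", "C"), data.frame(
    from = c("A", "A", "B"), to = c("B", "C", "C"),
    weight = c(10, 0.1, 10), stringsAsFactors = FALSE))
  # d(A, C) = min(10, 0.1 + 0.1) = 0.2 via B
  expect_equal(unname(weighted_closeness(g, "harmonic")["A"]), 1 / 0.1 + 1 / 0.2)

  expect_error(weighted_closeness(weighted_graph("A", data.frame(
    from = character(), to = character(), weight = numeric())), "harmonic"),
    NA)
})

test_that("betweenness is 1 at a star centre and 0 at leaves", {
  b <- weighted_betweenness(star_wg(5))
  expect_equal(unname(b["H"]), 1)
  expect_true(all(b[-1] == 0))
})

test_that("degree strength has the closed form and mean-normalized scale invariance", {
  st <- star_wg(4, w = 0.5)
  raw <- degree_strength(st, normalizer = "none")
  expect_equal(unname(raw["H"]), 4 * 0.5)
  expect_equal(unname(raw["L1"]), 0.5)

  g1 <- triangle_wg(c(0.2, 0.5, 0.9))
  g2 <- triangle_wg(c(0.2, 0.5, 0.9) * 7)
  expect_equal(degree_strength(g1), degree_strength(g2))
})

test_that("local clustering is 1 in a triangle and 0 at a star centre", {
  expect_equal(unname(local_clustering(triangle_wg())), rep(1, 3))
  expect_equal(unname(local_clustering(star_wg(5))["H"]), 0)
})

test_that("topological importance is symmetric on an edge and hub-dominant", {
  se <- weighted_graph(c("A", "B"), data.frame(from = "A", to = "B",
                                               weight = 1))
  ti <- topological_importance(se)
  expect_equal(unname(ti["A"]), unname(ti["B"]))

  ti_star <- topological_importance(star_wg(6))
  expect_true(all(ti_star["H"] > ti_star[-1]))

  expect_error(topological_importance(se, steps = 0), "steps")
})

test_that("indices agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (i in 1:30) {
    g <- random_connected_wg(sample(4:8, 1))
    w <- wg_matrix(g)
    expect_equal(unname(weighted_closeness(g, "harmonic")),
                 oracle_harmonic_closeness(w), tolerance = 1e-12)
    expect_equal(unname(weighted_closeness(g, "classic")),
                 oracle_classic_closeness(w), tolerance = 1e-12)
    expect_equal(unname(weighted_betweenness(g)), oracle_betweenness(w),
                 tolerance = 1e-12)
    expect_equal(unname(local_clustering(g)), oracle_local_clustering(w),
                 tolerance = 1e-12)
    expect_equal(unname(topological_importance(g, 2)),
                 oracle_topological_importance(w, 2), tolerance = 1e-12)
    expect_equal(unname(topological_importance(g, 3)),
                 oracle_topological_importance(w, 3), tolerance = 1e-12)
  }
})

test_that("scaling edge weights rescales distances but not rankings", {
  set.seed(101)
  g <- random_connected_wg(7)
  c1 <- weighted_closeness(g, "harmonic")
  g2 <- g
  g2$edges$weight <- g$edges$weight * 3
  c2 <- weighted_closeness(g2, "harmonic")
  expect_equal(unname(c2), unname(c1) * 3, tolerance = 1e-12)
  expect_equal(order(-c1), order(-c2))
  expect_equal(weighted_betweenness(g), weighted_betweenness(g2))
})

test_that("global statistics satisfy their internal identities", {
  k4 <- weighted_graph(letters[1:4], data.frame(
    from = t(combn(letters[1:4], 2))[, 1],
    to = t(combn(letters[1:4], 2))[, 2], weight = 1,
    stringsAsFactors = FALSE))
  gs <- global_stats(k4)
  expect_equal(gs$density, 1)
  expect_equal(gs$clustering_coefficient, 1)
  expect_equal(gs$diameter, 1)
  expect_equal(gs$shortest_paths_count, 12)

  set.seed(55)
  for (i in 1:10) {
    g <- random_connected_wg(sample(5:9, 1))
    gs <- global_stats(g)
    n <- gs$n_nodes
    expect_equal(gs$shortest_paths_count, n * (n - 1)) # connected
    expect_equal(gs$density * (n - 1), gs$avg_neighbors, tolerance = 1e-12)
    expect_true(gs$radius <= gs$diameter)
    expect_true(all(is.finite(unlist(gs))))
  }

  # hop-count definitions are insensitive to edge weights
  heavy <- triangle_wg(w = 0.1)
  gsh <- global_stats(heavy)
  expect_equal(gsh$diameter, 1)
  expect_equal(gsh$characteristic_path_length, 1)

  expect_error(global_stats(weighted_graph(character(), data.frame(
    from = character(), to = character(), weight = numeric()))), "empty")
})

test_that("disconnected graphs are handled per component with a warning", {
  g <- weighted_graph(c("A", "B", "C", "D"), data.frame(
    from = c("A", "C"), to = c("B", "D"), weight = 1,
    stringsAsFactors = FALSE))
  expect_warning(cl <- weighted_closeness(g, "classic"), "disconnected")
  expect_equal(unname(cl), rep(1, 4)) # each component is a single edge
  gs <- global_stats(g)
  expect_equal(gs$connected_components, 2)
  expect_equal(gs$shortest_paths_count, 4) # only within-component pairs
})

test_that("consensus ranking is monotone in agreement and finds unanimous genes", {
  set.seed(91)
  g <- random_connected_wg(10)
  tt <- topology_table(g)
  all4 <- consensus_rank(tt, top_k = 4, agreement = 4)
  all5 <- consensus_rank(tt, top_k = 4, agreement = 5)
  expect_true(all(all5$gene[all5$central] %in% all4$gene[all4$central]))

  # identical rankings across indices: every top-k gene is central
  nodes <- paste0("N", 1:6)
  tt2 <- tt[1:6, ]
  tt2$gene <- nodes
  for (cn in grep("^rank_", names(tt2), value = TRUE))
    tt2[[cn]] <- 1:6
  tt2$closeness <- 6:1
  class(tt2) <- c("topology_table", "data.frame")
  cr <- consensus_rank(tt2, top_k = 3, agreement = 4)
  expect_equal(nrow(cr), 3)
  expect_true(all(cr$central))

  expect_warning(consensus_rank(tt, top_k = 50), "clamped")
})
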