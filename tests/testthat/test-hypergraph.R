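test_that("hypergraph assembly canonicalizes, dedupes and drops self-edges", {
  ev <- data.frame(gene_a = c("B", "A", "A", "C"),
                   gene_b = c("A", "B", "A", "B"),
                   category = c("physical", "pathways", "physical", "genetic"),
                   weight = c(0.8, 0.6, 0.5, 0.9),
                   sign = c(1L, -1L, 1L, 1L), stringsAsFactors = FALSE)
  expect_warning(h <- build_hypergraph(ev), "self-edge")
  expect_equal(nrow(h$edges), 3)
  expect_true(all(h$edges$gene_a < h$edges$gene_b))

  # two categories on the same pair -> one agglomerated edge with n = 2
  g <- agglomerate(h)
  ab <- g$edges[g$edges$from == "A" & g$edges$to == "B", ]
  expect_equal(ab$n_evidence, 2L)

  dup <- rbind(ev[2, ], ev[2, ])
  expect_message(h2 <- build_hypergraph(dup), "deduplicated 1")
  expect_equal(nrow(h2$edges), 1)

  bad <- ev[2, ]; bad$weight <- 1.5
  expect_error(build_hypergraph(bad), "\\(0, 1\\]")
})

test_that("agglomeration follows W = exp(n) * mean(weights)", {
  mk <- function(weights) {
    ev <- data.frame(gene_a = "A", gene_b = "B",
                     category = paste0("c", seq_along(weights)),
                     weight = weights, sign = 1L, stringsAsFactors = FALSE)
    agglomerate(build_hypergraph(ev))$edges$weight
  }
  expect_equal(mk(0.5), exp(1) * 0.5)
  expect_equal(mk(c(1, 1)), exp(2))

  set.seed(19)
  for (i in 1:50) {
    w <- stats::runif(sample(1:6, 1), 0.05, 1)
    expect_equal(mk(w), exp(length(w)) * mean(w))
  }

  # strictly increasing in evidence count at fixed mean weight
  for (n in 1:5) expect_lt(mk(rep(0.4, n)), mk(rep(0.4, n + 1)))

  # adding an evidence of weight >= the current mean strictly increases W
  for (i in 1:25) {
    w <- stats::runif(sample(1:5, 1), 0.05, 0.9)
    extra <- stats::runif(1, mean(w), 1)
    expect_gt(mk(c(w, extra)), mk(w))
  }
})

test_that("agglomeration is symmetric and order-invariant, conserving counts", {
  set.seed(23)
  genes <- LETTERS[1:6]
  pairs <- t(combn(genes, 2))
  # random evidence rows with randomized endpoint order
  ev <- do.call(rbind, lapply(1:40, function(i) {
    p <- sample(pairs[sample(nrow(pairs), 1), ])
    data.frame(gene_a = p[1], gene_b = p[2],
               category = sample(letters, 1),
               weight = round(stats::runif(1, 0.1, 1), 3),
               sign = sample(c(-1L, 1L), 1), stringsAsFactors = FALSE)
  }))
  g1 <- agglomerate(build_hypergraph(ev))
  g2 <- agglomerate(build_hypergraph(ev[sample(nrow(ev)), ]))
  expect_identical(g1$edges, g2$edges)

  h <- build_hypergraph(ev)
  expect_setequal(g1$nodes, h$nodes)
  key <- unique(paste(h$edges$gene_a, h$edges$gene_b))
  expect_equal(nrow(g1$edges), length(key))
})

test_that("pairs without evidence have no edge", {
  ev <- data.frame(gene_a = "A", gene_b = "B", category = "c1",
                   weight = 0.5, sign = 1L, stringsAsFactors = FALSE)
  h <- build_hypergraph(ev, node_weights = matrix(
    1, 3, 1, dimnames = list(c("A", "B", "C"), "H_C")))
  g <- agglomerate(h)
  expect_equal(nrow(g$edges), 1)
})

test_that("edge signs summarize by majority with ties unsigned", {
  ev <- data.frame(gene_a = c("A", "A", "A", "B", "B"),
                   gene_b = c("B", "B", "B", "C", "C"),
                   category = c("c1", "c2", "c3", "c1", "c2"),
                   weight = 0.5, sign = c(1L, 1L, -1L, 1L, -1L),
                   stringsAsFactors = FALSE)
  s <- edge_sign_summary(build_hypergraph(ev))
  expect_equal(s$sign[s$gene_a == "A"], 1L)   # (+, +, -) -> +
  expect_equal(s$sign[s$gene_a == "B"], 0L)   # (+, -) -> unsigned

  pos <- ev; pos$sign <- 1L
  expect_true(all(edge_sign_summary(build_hypergraph(pos))$sign == 1L))
})

test_that("synthetic evidence round-trips into the same weighted graph", {
  dir <- withr::local_tempdir()
  ev <- gen_evidence_hypergraph(sprintf("G%02d", 1:12), edge_density = 0.2,
                                seed = 41)$evidence
  write_evidence(ev, file.path(dir, "ev.tsv"))
  g1 <- agglomerate(build_hypergraph(ev))
  g2 <- agglomerate(build_hypergraph(read_evidence(file.path(dir, "ev.tsv"))))
  expect_equal(g1$edges, g2$edges)
  expect_identical(g1$nodes, g2$nodes)
})

test_that("unknown evidence genes are dropped or added per configuration", {
  ev <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                   category = "c1", weight = 0.5, sign = 1L,
                   stringsAsFactors = FALSE)
  nw <- matrix(1:2, 2, 1, dimnames = list(c("A", "B"), "H_C"))
  h_add <- build_hypergraph(ev, node_weights = nw, unknown_genes = "add")
  expect_setequal(h_add$nodes, c("A", "B", "C", "D"))
  expect_equal(unname(h_add$node_weights["C", 1]), 0)
  h_drop <- build_hypergraph(ev, node_weights = nw, unknown_genes = "drop")
  expect_setequal(h_drop$nodes, c("A", "B"))
  expect_equal(nrow(h_drop$edges), 1)
})
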