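#' Scale fold-change profiles by gene closeness
#'
#' Weights each gene's contrast profile by its closeness centrality, so that
#' the subsequent clustering groups genes by both expression behaviour and
#' network centrality: `scaled_profile(g) = profile(g) * closeness(g)`.
#' Profiles are the signed fold changes by default; the log2 ratios can be
#' used instead.
#'
#' @param cm A [contrast_matrix()].
#' @param closeness Named numeric vector of closeness values (e.g. from
#'   [weighted_closeness()]); genes of `cm` without a closeness value are
#'   dropped with a warning.
#' @param use_log2 Scale the log2 ratios instead of the signed fold changes.
#' @return Numeric matrix (genes x contrasts) with gene row names.
#' @export
scale_by_closeness <- function(cm, closeness, use_log2 = FALSE) {
  if (!inherits(cm, "contrast_matrix")) stopf("'cm' must be a contrast_matrix")
  if (is.null(names(closeness))) stopf("'closeness' must be named by gene")
  prof <- if (use_log2) cm$log2_ratio else cm$signed_fc
  have <- cm$genes %in% names(closeness)
  if (!all(have))
    warnf("dropping %d gene(s) without a closeness value", sum(!have))
  prof <- prof[have, , drop = FALSE]
  prof * as.numeric(closeness[rownames(prof)])
}

#' Hierarchical clustering of scaled expression profiles
#'
#' Agglomerative clustering of gene profiles under the squared Euclidean
#' dissimilarity, cut into `k` groups. Ward linkage (`"ward.D"` on squared
#' distances, the classic Ward criterion) is the default; average linkage is
#' available. Genes are sorted lexicographically before clustering so the
#' result does not depend on input order.
#'
#' @param profiles Numeric matrix with gene row names (e.g. from
#'   [scale_by_closeness()]).
#' @param k Number of clusters (default 5); must not exceed the number of
#'   genes.
#' @param linkage `"ward"` or `"average"`.
#' @param auto_k If TRUE, `k` is chosen by the largest gap in merge heights
#'   instead of the fixed value.
#' @return An object of class `cluster_set`: a list with `assignment` (named
#'   integer vector, gene -> cluster in 1..k), `k`, `tree` (the `hclust`
#'   object) and `heights`.
#' @export
hcluster_profiles <- function(profiles, k = 5,
                              linkage = c("ward", "average"),
                              auto_k = FALSE) {
  linkage <- match.arg(linkage)
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) stopf("'profiles' must have gene row names")
  n <- nrow(profiles)
  k <- check_count(k, "k", 1L)
  if (k > n) stopf("'k' (%d) exceeds the number of genes (%d)", k, n)
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- stats::dist(profiles)^2
  tree <- stats::hclust(d, method = switch(linkage, ward = "ward.D",
                                           average = "average"))
  if (auto_k && n > 2) {
    gaps <- diff(tree$height)
    k <- n - which.max(gaps)
  }
  assignment <- stats::cutree(tree, k = k)
  structure(list(assignment = assignment, k = k, tree = tree,
                 heights = tree$height),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d genes in %d clusters (sizes: %s)\n",
              length(x$assignment), x$k,
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

#' Gene-set over-representation of clusters
#'
#' Hypergeometric upper-tail test of the overlap between every cluster and
#' every gene set, against a fixed gene universe, with Benjamini-Hochberg
#' adjustment across all (cluster, set) pairs. A cluster is flagged
#' significantly associated when any of its adjusted p-values falls below
#' `alpha`.
#'
#' @param clusters A [hcluster_profiles()] result, or a named integer vector
#'   of cluster labels.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of all genes under consideration
#'   (non-empty); sets and clusters are intersected with it.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Data frame with one row per (cluster, set): `cluster`, `set`,
#'   `overlap`, `set_size`, `cluster_size`, `universe_size`, `p_value`,
#'   `adjusted_p`, `significant`.
#' @export
enrich_sets <- function(clusters, sets, universe, alpha = 0.05) {
  assignment <- if (inherits(clusters, "cluster_set"))
    clusters$assignment else clusters
  if (is.null(names(assignment))) stopf("cluster labels must be named by gene")
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stopf("'universe' must be non-empty")
  if (is.null(names(sets)) || length(sets) == 0)
    stopf("'sets' must be a non-empty named list")
  check_number(alpha, "alpha", 0, 1, open_min = TRUE)
  u <- length(universe)
  members <- split(names(assignment), assignment)
  members <- lapply(members, intersect, universe)
  sets_u <- lapply(sets, intersect, universe)
  rows <- list()
  for (cl in names(members)) {
    k_size <- length(members[[cl]])
    for (sn in names(sets_u)) {
      m <- length(sets_u[[sn]])
      ov <- length(intersect(members[[cl]], sets_u[[sn]]))
      p <- stats::phyper(ov - 1, m, u - m, k_size, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, set = sn, overlap = ov, set_size = m,
                   cluster_size = k_size, universe_size = u, p_value = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha
  out <- out[order(out$cluster, out$adjusted_p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
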