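# Synthetic-data generators. The raw study data (pooled patient/control RNA
# libraries, serum-shock qRT-PCR series, the assembled interaction network)
# are not deposited anywhere, so every downstream stage is exercised on
# synthetic inputs carrying a planted ground truth: cluster structure in the
# contrast profiles, known rhythm parameters in the time series, and hub
# genes in the evidence hypergraph.

#' Ground-truth record for synthetic data
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param cluster_assignment Named integer vector, gene -> cluster label.
#' @param hub_genes Character vector of planted hub genes.
#' @param rhythm_params Data frame of per-(gene, condition) rhythm truth.
#' @param contrast_effects Cluster-by-contrast matrix of mean log2 ratios.
#' @param seed Integer seed the data were generated with.
#' @return An object of class `synthetic_truth` (a list of the above).
#' @export
synthetic_truth <- function(gene_ids, cluster_assignment = NULL,
                            hub_genes = NULL, rhythm_params = NULL,
                            contrast_effects = NULL, seed = NULL) {
  if (!is.null(cluster_assignment)) {
    if (is.null(names(cluster_assignment)) ||
        !setequal(names(cluster_assignment), gene_ids))
      stopf("'cluster_assignment' must be named by every gene exactly once")
  }
  structure(list(gene_ids = as.character(gene_ids),
                 cluster_assignment = cluster_assignment,
                 hub_genes = hub_genes, rhythm_params = rhythm_params,
                 contrast_effects = contrast_effects, seed = seed),
            class = "synthetic_truth")
}

#' Default cluster effect matrix for contrast simulation
#'
#' Five mean log2-ratio patterns over the five contrasts, one per planted
#' cluster. Magnitudes range over 0.5-1.2 log2 units (fold changes of about
#' 1.4-2.3, the range the sequencing comparisons report for regulated clock
#' genes) and every entry is bounded away from zero so that the sign of the
#' fold change is stable under the default noise level.
#'
#' @param k_clusters Number of clusters (at most 5 for the built-in
#'   patterns).
#' @return A `k_clusters` x 5 matrix with contrast labels as column names.
#' @export
default_effect_matrix <- function(k_clusters = 5) {
  k_clusters <- check_count(k_clusters, "k_clusters", 1L)
  base <- rbind(c( 1.0,  1.2,  0.8,  0.6,  0.9),
                c(-1.0, -0.8, -1.2, -0.6, -0.9),
                c( 0.9, -0.9,  0.9, -0.9,  0.9),
                c(-0.7,  0.8, -0.6,  1.0, -0.8),
                c( 0.6,  0.5,  0.7, -1.2, -1.0))
  if (k_clusters > nrow(base))
    stopf("built-in patterns cover at most %d clusters; supply 'effect_matrix'",
          nrow(base))
  m <- base[seq_len(k_clusters), , drop = FALSE]
  dimnames(m) <- list(paste0("cluster", seq_len(k_clusters)), CONTRAST_LABELS)
  m
}

# Vectorized two-sided Welch t-test p-values for two groups stored as
# n_obs x n_rep matrices of replicates.
welch_p <- function(g1, g2) {
  n <- ncol(g1)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, stats::var); v2 <- apply(g2, 1, stats::var)
  se2 <- v1 / n + v2 / n
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n)^2 / (n - 1) + (v2 / n)^2 / (n - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Simulate gene-by-contrast expression profiles with planted clusters
#'
#' Each gene is assigned (round-robin) to one of `k_clusters` clusters; its
#' five log2 ratios are the cluster's mean effects plus Gaussian noise of
#' standard deviation `noise_sd`. P-values come from a Welch t-test on
#' simulated per-group replicates whose spread is calibrated so the observed
#' log2 ratio has standard deviation exactly `noise_sd`; genes whose effect
#' exceeds the noise therefore receive small p-values, null genes
#' near-uniform ones. With `noise_sd = 0` the ratios equal the effects
#' exactly and p-values degenerate to 1e-300 (effect present) or 1 (absent).
#'
#' @param n_genes Number of genes.
#' @param k_clusters Number of planted clusters (`<= n_genes`).
#' @param effect_matrix `k_clusters` x 5 matrix of mean log2 ratios; default
#'   [default_effect_matrix()].
#' @param noise_sd Standard deviation of the log2-ratio noise (log2 units).
#' @param n_replicates Simulated replicates per group for the p-value rule.
#' @param seed Integer random seed.
#' @return A list with `matrix` (a [contrast_matrix()]) and `truth`
#'   (a [synthetic_truth()]).
#' @export
gen_contrast_profiles <- function(n_genes, k_clusters = 5,
                                  effect_matrix = default_effect_matrix(k_clusters),
                                  noise_sd = 0.2, n_replicates = 3, seed) {
  n_genes <- check_count(n_genes, "n_genes", 1L)
  k_clusters <- check_count(k_clusters, "k_clusters", 1L)
  n_replicates <- check_count(n_replicates, "n_replicates", 2L)
  check_number(noise_sd, "noise_sd", 0)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  if (k_clusters > n_genes) stopf("'k_clusters' must not exceed 'n_genes'")
  effect_matrix <- as.matrix(effect_matrix)
  if (nrow(effect_matrix) != k_clusters ||
      ncol(effect_matrix) != length(CONTRAST_LABELS))
    stopf("'effect_matrix' must be %d x %d", k_clusters,
          length(CONTRAST_LABELS))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  cluster <- rep_len(seq_len(k_clusters), n_genes)
  mu <- effect_matrix[cluster, , drop = FALSE]
  nc <- length(CONTRAST_LABELS)
  if (noise_sd == 0) {
    l2 <- mu
    p <- ifelse(abs(mu) > 0, 1e-300, 1)
  } else {
    # replicate sd chosen so mean(g2) - mean(g1) has sd = noise_sd
    rep_sd <- noise_sd * sqrt(n_replicates / 2)
    ncell <- n_genes * nc
    g1 <- matrix(stats::rnorm(ncell * n_replicates, 0, rep_sd),
                 ncell, n_replicates)
    g2 <- matrix(stats::rnorm(ncell * n_replicates, as.vector(mu), rep_sd),
                 ncell, n_replicates)
    l2 <- matrix(rowMeans(g2) - rowMeans(g1), n_genes, nc)
    p <- matrix(welch_p(g1, g2), n_genes, nc)
  }
  dimnames(l2) <- dimnames(p) <- list(genes, CONTRAST_LABELS)
  cm <- contrast_matrix(2^l2, p)
  truth <- synthetic_truth(genes,
                           cluster_assignment = stats::setNames(cluster, genes),
                           contrast_effects = effect_matrix, seed = seed)
  list(matrix = cm, truth = truth)
}

#' Random rhythm parameters for time-series simulation
#'
#' Draws MESOR, amplitude and acrophase for each (gene, condition) pair in
#' ranges matching the fitted rhythms the serum-shock experiments report
#' (MESOR about 0.3-0.9, amplitude 0.03-0.5 relative units, acrophase
#' anywhere on the circle).
#'
#' @param genes Character vector of gene identifiers.
#' @param conditions Character vector of condition labels.
#' @param noise_sd Observation noise standard deviation (expression units).
#' @param seed Integer random seed.
#' @return Data frame with columns `gene`, `condition`, `mesor`, `amplitude`,
#'   `acrophase_deg`, `noise_sd`.
#' @export
random_rhythm_params <- function(genes,
                                 conditions = c("control", "hunter",
                                                "hunter_treated"),
                                 noise_sd = 0.05, seed) {
  check_number(noise_sd, "noise_sd", 0)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  set.seed(seed)
  grid <- expand.grid(gene = genes, condition = conditions,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  grid$mesor <- stats::runif(n, 0.3, 0.9)
  grid$amplitude <- stats::runif(n, 0.03, 0.5)
  grid$acrophase_deg <- stats::runif(n, 0, 360)
  grid$noise_sd <- noise_sd
  grid
}

#' Simulate serum-shock time series with known rhythm parameters
#'
#' Generates `value(t) = mesor + amplitude * cos(2*pi*t/24 -
#' acrophase_deg*pi/180) + N(0, noise_sd)` for every (gene, condition) row of
#' `rhythm_params`, at the post-shock harvest times of the study design
#' (1, 4, 10, 16, 22 and 28 h by default) and `n_replicates` replicates per
#' time point. With `standardize = TRUE` each replicate series is divided by
#' its value at the first time point (expression relative to the 1-h
#' reference); the default keeps raw values so the planted parameters are
#' recoverable exactly at zero noise.
#'
#' @param rhythm_params Data frame as returned by [random_rhythm_params()].
#' @param timepoints Sampling times in hours (non-empty).
#' @param n_replicates Replicates per time point.
#' @param seed Integer random seed.
#' @param period_h Rhythm period in hours (default 24).
#' @param standardize Divide each replicate series by its first-time-point
#'   value (default FALSE).
#' @return A list with `series` (data frame: gene, condition, replicate,
#'   time_h, value) and `truth` (a [synthetic_truth()]).
#' @export
gen_timeseries <- function(rhythm_params,
                           timepoints = c(1, 4, 10, 16, 22, 28),
                           n_replicates = 3, seed, period_h = 24,
                           standardize = FALSE) {
  need <- c("gene", "condition", "mesor", "amplitude", "acrophase_deg",
            "noise_sd")
  if (!all(need %in% names(rhythm_params)))
    stopf("'rhythm_params' must have columns %s", paste(need, collapse = ", "))
  if (length(timepoints) == 0) stopf("'timepoints' must be non-empty")
  if (any(!is.finite(timepoints)) || any(timepoints < 0))
    stopf("'timepoints' must be non-negative")
  n_replicates <- check_count(n_replicates, "n_replicates", 1L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  if (any(rhythm_params$noise_sd < 0)) stopf("'noise_sd' must be >= 0")
  if (any(rhythm_params$acrophase_deg < 0 |
          rhythm_params$acrophase_deg >= 360))
    stopf("'acrophase_deg' must lie in [0, 360)")
  set.seed(seed)
  timepoints <- sort(timepoints)
  omega <- 2 * pi / period_h
  rows <- vector("list", nrow(rhythm_params))
  for (i in seq_len(nrow(rhythm_params))) {
    pr <- rhythm_params[i, ]
    for (r in seq_len(n_replicates)) {
      mu <- pr$mesor + pr$amplitude *
        cos(omega * timepoints - pr$acrophase_deg * pi / 180)
      v <- mu + stats::rnorm(length(timepoints), 0, pr$noise_sd)
      if (standardize) v <- v / v[1]
      rows[[i]] <- rbind(rows[[i]],
                         data.frame(gene = pr$gene, condition = pr$condition,
                                    replicate = r, time_h = timepoints,
                                    value = v, stringsAsFactors = FALSE))
    }
  }
  series <- do.call(rbind, rows)
  rownames(series) <- NULL
  truth <- synthetic_truth(unique(rhythm_params$gene),
                           rhythm_params = rhythm_params, seed = seed)
  list(series = series, truth = truth)
}

#' Simulate a multi-evidence interaction hypergraph with planted hubs
#'
#' For every evidence category, each gene pair independently receives an
#' evidence edge with probability `edge_density` (boosted, capped at 1, for
#' pairs touching a planted hub), a reliability weight drawn uniformly from
#' `weight_range`, and a sign. Pairs hit in several categories end up
#' connected by multiple parallel edges, the situation the agglomeration step
#' rewards. The default per-category density of 0.024 over six categories
#' yields a combined simple-graph density near 0.135, the density of the
#' study's 190-gene network.
#'
#' @param genes Character vector of gene identifiers (at least 2).
#' @param n_categories Number of evidence categories; 6 uses the named
#'   default categories (domains, coexpression, genetic, pathways, physical,
#'   predicted).
#' @param edge_density Per-category edge probability in (0, 1].
#' @param weight_range Length-2 numeric, reliability weight bounds within
#'   (0, 1].
#' @param hub_genes Genes whose incident edge probability is multiplied by
#'   `hub_boost`; must be a subset of `genes`.
#' @param hub_boost Multiplier (>= 1) on the edge probability of hub pairs.
#' @param prob_positive Probability that an evidence edge carries a positive
#'   sign.
#' @param seed Integer random seed.
#' @return A list with `evidence` (data frame: gene_a, gene_b, category,
#'   weight, sign) and `truth` (a [synthetic_truth()]).
#' @export
gen_evidence_hypergraph <- function(genes, n_categories = 6,
                                    edge_density = 0.024,
                                    weight_range = c(0.5, 1),
                                    hub_genes = character(),
                                    hub_boost = 1, prob_positive = 0.5,
                                    seed) {
  genes <- as.character(genes)
  if (length(genes) < 2) stopf("at least 2 genes are required")
  n_categories <- check_count(n_categories, "n_categories", 1L)
  check_number(edge_density, "edge_density", 0, 1, open_min = TRUE)
  check_number(hub_boost, "hub_boost", 1)
  check_number(prob_positive, "prob_positive", 0, 1)
  if (length(weight_range) != 2 || any(weight_range <= 0) ||
      any(weight_range > 1) || weight_range[1] > weight_range[2])
    stopf("'weight_range' must be increasing bounds within (0, 1]")
  if (!all(hub_genes %in% genes))
    stopf("hub genes not in the gene list: %s",
          paste(setdiff(hub_genes, genes), collapse = ", "))
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  categories <- if (n_categories == length(EVIDENCE_CATEGORIES))
    EVIDENCE_CATEGORIES else paste0("category", seq_len(n_categories))
  set.seed(seed)
  pairs <- t(utils::combn(genes, 2))
  is_hub_pair <- pairs[, 1] %in% hub_genes | pairs[, 2] %in% hub_genes
  p_edge <- ifelse(is_hub_pair, pmin(1, edge_density * hub_boost),
                   edge_density)
  out <- vector("list", n_categories)
  for (k in seq_len(n_categories)) {
    keep <- stats::runif(nrow(pairs)) < p_edge
    m <- sum(keep)
    if (m == 0) next
    out[[k]] <- data.frame(
      gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
      category = categories[k],
      weight = stats::runif(m, weight_range[1], weight_range[2]),
      sign = ifelse(stats::runif(m) < prob_positive, 1L, -1L),
      stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, out)
  if (is.null(evidence))
    evidence <- data.frame(gene_a = character(), gene_b = character(),
                           category = character(), weight = numeric(),
                           sign = integer(), stringsAsFactors = FALSE)
  rownames(evidence) <- NULL
  truth <- synthetic_truth(genes, hub_genes = hub_genes, seed = seed)
  list(evidence = evidence, truth = truth)
}

#' Gene-set annotations matched to planted clusters, plus decoys
#'
#' Builds one gene set per planted cluster containing a `coverage` fraction
#' of its members (sampled without replacement) and `decoy_sets` additional
#' sets of random genes of comparable size, for exercising enrichment without
#' an external annotation database.
#'
#' @param truth A [synthetic_truth()] with a `cluster_assignment`.
#' @param coverage Fraction of each cluster included in its matched set,
#'   in (0, 1].
#' @param decoy_sets Number of random decoy sets (>= 0).
#' @param seed Integer random seed.
#' @return Named list of character vectors (GMT-compatible); planted sets are
#'   named `planted_cluster_<k>`, decoys `decoy_<i>`.
#' @export
gen_annotation_sets <- function(truth, coverage = 0.8, decoy_sets = 10,
                                seed) {
  if (!inherits(truth, "synthetic_truth") ||
      is.null(truth$cluster_assignment))
    stopf("'truth' must be a synthetic_truth with a cluster assignment")
  check_number(coverage, "coverage", 0, 1, open_min = TRUE)
  decoy_sets <- check_count(decoy_sets, "decoy_sets", 0L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  set.seed(seed)
  clusters <- split(names(truth$cluster_assignment),
                    truth$cluster_assignment)
  planted <- lapply(clusters, function(g) {
    n_take <- max(1L, ceiling(coverage * length(g)))
    sort(sample(g, n_take))
  })
  names(planted) <- paste0("planted_cluster_", names(clusters))
  decoys <- list()
  if (decoy_sets > 0) {
    size <- max(2L, round(stats::median(lengths(clusters))))
    decoys <- lapply(seq_len(decoy_sets), function(i)
      sort(sample(truth$gene_ids, min(size, length(truth$gene_ids)))))
    names(decoys) <- sprintf("decoy_%02d", seq_len(decoy_sets))
  }
  c(planted, decoys)
}
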