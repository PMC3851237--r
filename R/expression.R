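#' Convert an expression ratio to a signed fold change
#'
#' Expression ratios below one are reported as negative fold changes so that
#' up- and down-regulation are symmetric in magnitude: a ratio of 0.5 becomes
#' a fold change of -2. Ratios of at least one are returned unchanged.
#'
#' @param ratio Numeric vector of positive expression ratios
#'   (test / reference).
#' @return Numeric vector of signed fold changes with magnitude >= 1.
#' @seealso [signed_fc_to_ratio()] for the inverse mapping.
#' @examples
#' ratio_to_signed_fc(c(1, 0.5, 2))
#' @export
ratio_to_signed_fc <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    stopf("'ratio' must contain positive finite values")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Convert a signed fold change back to an expression ratio
#'
#' Inverse of [ratio_to_signed_fc()]: positive fold changes are returned as
#' is, negative fold changes fc map to the ratio -1/fc.
#'
#' @param fc Numeric vector of signed fold changes with magnitude >= 1.
#' @return Numeric vector of positive ratios.
#' @export
signed_fc_to_ratio <- function(fc) {
  if (!is.numeric(fc) || any(!is.finite(fc)) || any(abs(fc) < 1))
    stopf("'fc' must contain finite values with magnitude >= 1")
  ifelse(fc >= 1, fc, -1 / fc)
}

#' Relative expression from a delta-delta-Ct value
#'
#' Relative quantification of qRT-PCR assays: expression relative to a
#' housekeeping gene and a calibrator condition is `2^(-ddct)`.
#'
#' @param ddct Numeric vector of delta-delta-Ct values (cycles).
#' @return Numeric vector of relative expression values (dimensionless).
#' @examples
#' ddct_expression(c(0, 1, -2)) # 1, 0.5, 4
#' @export
ddct_expression <- function(ddct) {
  if (!is.numeric(ddct) || any(!is.finite(ddct)))
    stopf("'ddct' must contain finite values")
  2^(-ddct)
}

#' Construct a contrast matrix of expression ratios and p-values
#'
#' Container for a genes-by-contrasts table of expression ratios with
#' per-contrast p-values. Log2 ratios and signed fold changes are derived on
#' construction, so the three representations are always consistent.
#'
#' @param ratio Numeric matrix of positive ratios, genes in rows, contrasts
#'   in columns.
#' @param p_value Numeric matrix of p-values in `[0, 1]`, same shape.
#' @param contrasts Character vector of contrast labels; defaults to the
#'   column names of `ratio`.
#' @param genes Character vector of gene identifiers; defaults to the row
#'   names of `ratio`.
#' @return An object of class `contrast_matrix`: a list with elements
#'   `genes`, `contrasts`, `ratio`, `log2_ratio`, `signed_fc`, `p_value`.
#' @export
contrast_matrix <- function(ratio, p_value, contrasts = colnames(ratio),
                            genes = rownames(ratio)) {
  ratio <- as.matrix(ratio)
  p_value <- as.matrix(p_value)
  if (is.null(genes) || is.null(contrasts))
    stopf("'genes' and 'contrasts' must be supplied or present as dimnames")
  if (!all(dim(ratio) == dim(p_value)))
    stopf("'ratio' and 'p_value' must have identical dimensions")
  if (length(genes) != nrow(ratio) || length(contrasts) != ncol(ratio))
    stopf("dimnames do not match matrix dimensions")
  if (anyDuplicated(genes)) stopf("gene identifiers must be unique")
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stopf("'ratio' must be positive and finite")
  if (any(!is.finite(p_value)) || any(p_value < 0) || any(p_value > 1))
    stopf("'p_value' must lie in [0, 1]")
  dimnames(ratio) <- dimnames(p_value) <- list(genes, contrasts)
  structure(list(genes = as.character(genes),
                 contrasts = as.character(contrasts),
                 ratio = ratio,
                 log2_ratio = log2(ratio),
                 signed_fc = ifelse(ratio >= 1, ratio, -1 / ratio),
                 p_value = p_value),
            class = "contrast_matrix")
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat(sprintf("contrast_matrix: %d genes x %d contrasts (%s)\n",
              length(x$genes), length(x$contrasts),
              paste(x$contrasts, collapse = ", ")))
  invisible(x)
}

#' Partition genes of one contrast by significance and direction
#'
#' Applies the study's significance threshold to a single contrast and labels
#' each gene `up` (p < alpha and positive fold change), `down` (p < alpha and
#' negative fold change) or `not_significant`. The default threshold of 0.001
#' is the one used for sequencing-derived comparisons; qRT-PCR comparisons
#' conventionally use 0.05.
#'
#' @param cm A [contrast_matrix()].
#' @param contrast One contrast label present in `cm$contrasts`.
#' @param alpha Significance threshold in (0, 1); genes pass with p < alpha.
#' @return A data frame with columns `gene`, `ratio`, `signed_fc`, `p_value`,
#'   `status`.
#' @export
filter_significant <- function(cm, contrast, alpha = 0.001) {
  if (!inherits(cm, "contrast_matrix")) stopf("'cm' must be a contrast_matrix")
  check_number(alpha, "alpha", 0, 1, open_min = TRUE, open_max = TRUE)
  j <- match(contrast, cm$contrasts)
  if (is.na(j))
    stopf("unknown contrast '%s' (available: %s)", contrast,
          paste(cm$contrasts, collapse = ", "))
  sig <- cm$p_value[, j] < alpha
  dir <- ifelse(cm$log2_ratio[, j] > 0, "up", "down")
  data.frame(gene = cm$genes,
             ratio = unname(cm$ratio[, j]),
             signed_fc = unname(cm$signed_fc[, j]),
             p_value = unname(cm$p_value[, j]),
             status = ifelse(sig, dir, "not_significant"),
             stringsAsFactors = FALSE)
}

#' Screen genes by variation across the first principal components
#'
#' Feature screen for contrast profiles: the per-contrast standardized log2
#' ratio matrix is decomposed by PCA (genes as observations, contrasts as
#' variables) and genes are ranked by the Euclidean norm of their projection
#' onto the first `n_components` axes, i.e. by how much they vary along the
#' most varying directions of the data. The bottom `1 - keep_fraction` of
#' genes — those without a relevant expression change — are discarded. The
#' returned report carries each gene's coordinates on the leading axes for
#' plotting.
#'
#' @param cm A [contrast_matrix()] with at least two genes.
#' @param n_components Number of leading principal components used for the
#'   projection norm (default 3); must not exceed the number of contrasts.
#' @param keep_fraction Fraction of genes to retain, in (0, 1].
#' @return A list with `retained` (character vector of gene ids, in input
#'   order) and `report` (data frame: gene, one column per component,
#'   `proj_norm`, `retained`).
#' @export
select_features <- function(cm, n_components = 3, keep_fraction = 0.5) {
  if (!inherits(cm, "contrast_matrix")) stopf("'cm' must be a contrast_matrix")
  n_components <- check_count(n_components, "n_components", 1L)
  check_number(keep_fraction, "keep_fraction", 0, 1, open_min = TRUE)
  if (length(cm$genes) < 2) stopf("at least 2 genes are required")
  if (n_components > length(cm$contrasts))
    stopf("'n_components' (%d) exceeds the number of contrasts (%d)",
          n_components, length(cm$contrasts))
  x <- cm$log2_ratio
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1  # zero-variance contrast: centre only
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  proj_norm <- sqrt(rowSums(scores^2))
  n_keep <- ceiling(keep_fraction * length(cm$genes))
  ord <- order(-proj_norm, cm$genes)
  retained_idx <- sort(ord[seq_len(n_keep)])
  report <- data.frame(gene = cm$genes, stringsAsFactors = FALSE)
  for (k in seq_len(n_components)) report[[paste0("PC", k)]] <- scores[, k]
  report$proj_norm <- proj_norm
  report$retained <- seq_along(cm$genes) %in% retained_idx
  rownames(report) <- NULL
  list(retained = cm$genes[retained_idx], report = report,
       sdev = pca$sdev)
}
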