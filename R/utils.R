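# Internal helpers shared across modules.

# The five expression contrasts of the study design: disease vs control,
# 24 h / 144 h post-treatment vs control, and the two treatment-vs-untreated
# comparisons.
CONTRAST_LABELS <- c("H_C", "T1_C", "T2_C", "T1_H", "T2_H")

# Default evidence categories: protein domains, co-localization/co-expression,
# genetic interactions, pathway co-membership, physical interactions, and
# literature-predicted interactions.
EVIDENCE_CATEGORIES <- c("domains", "coexpression", "genetic",
                         "pathways", "physical", "predicted")

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         open_min = FALSE, open_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  lo_ok <- if (open_min) x > min else x >= min
  hi_ok <- if (open_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stopf("'%s' must lie in %s%g, %g%s", name,
          if (open_min) "(" else "[", min, max, if (open_max) ")" else "]")
  x
}

# Deterministic rank positions: highest value first, ties broken by higher
# closeness, then by lexicographic gene id. Returns rank 1..n.
rank_stable <- function(values, closeness, gene) {
  ord <- order(-values, -closeness, gene)
  r <- integer(length(values))
  r[ord] <- seq_along(ord)
  r
}

# Format numeric columns to 17 significant digits so TSV round trips are
# exact and repeated writes are byte-identical.
format_tsv_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(format_tsv_cols(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
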