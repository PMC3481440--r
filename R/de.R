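# Differential expression between a poor-prognosis classification and the
# good-prognosis group: Welch t-test on log2 values plus a linear fold-change
# filter (defaults 1.5x and p < 0.01; raw p-values, matching the procedure's
# use of uncorrected scans -- an optional BH column is available).

#' Differentially expressed genes between two sample groups
#'
#' Per gene: a two-sided t-test (Welch by default) on log2 expression and a
#' linear fold change `2^(mean_a - mean_b)`. A gene passes when the fold
#' change is at least `fc_cut` (or at most `1/fc_cut`; boundary inclusive)
#' and p is below `alpha`. Genes missing in more than half of either group,
#' or with fewer than 2 non-missing values on a side, are excluded and
#' counted in the `excluded` attribute.
#'
#' @param expression Expression `omics_matrix` (log2, batch-corrected).
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @param fc_cut Linear fold-change cutoff (> 1).
#' @param alpha t-test level.
#' @param equal_var Use the pooled-variance t-test instead of Welch.
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column.
#' @return Data frame sorted by ascending p: `gene`, `mean_a`, `mean_b`
#'   (log2), `fold_change` (linear, a vs b), `p_value`, `passes` (and
#'   `p_adjusted` when `adjust`). Attribute `excluded` counts skipped genes.
#' @export
differential_expression <- function(expression, group_a, group_b,
                                    fc_cut = 1.5, alpha = 0.01,
                                    equal_var = FALSE, adjust = FALSE) {
  stopifnot(fc_cut > 1)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  v <- expression$values
  a <- v[, intersect(group_a, colnames(v)), drop = FALSE]
  b <- v[, intersect(group_b, colnames(v)), drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each group needs at least 2 samples present in the matrix")
  na_ok <- rowSums(!is.na(a)) >= max(2L, ceiling(ncol(a) / 2)) &
           rowSums(!is.na(b)) >= max(2L, ceiling(ncol(b) / 2))
  excluded <- sum(!na_ok)
  genes <- rownames(v)[na_ok]
  av <- a[na_ok, , drop = FALSE]
  bv <- b[na_ok, , drop = FALSE]
  ma <- rowMeans(av, na.rm = TRUE)
  mb <- rowMeans(bv, na.rm = TRUE)
  p <- vapply(seq_along(genes), function(i) {
    suppressWarnings(two_sample_t(av[i, ], bv[i, ], equal_var = equal_var))
  }, numeric(1L))
  fc <- 2^(ma - mb)
  log_cut <- log2(fc_cut) - 1e-12
  passes <- abs(ma - mb) >= log_cut & p < alpha
  out <- data.frame(gene = genes, mean_a = ma, mean_b = mb,
                    fold_change = fc, p_value = p, passes = passes,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
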