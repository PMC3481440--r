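# Location/scale (L/S) batch-effect adjustment.
#
# Expression (log2): within each batch, values are re-centred on the pooled
# per-feature median and rescaled so the within-batch scale matches the
# pooled scale,
#     g* = M_i + (g - M_ij) * s_i / s_ij,
# with M the median and s either the standard deviation (default) or the
# MAD (consistency constant 1.4826, so the two agree on normal data).
#
# Methylation beta values are bounded in [0, 1] and mildly bimodal, so a
# piecewise-linear rescaling that pins 0, the batch median and 1 is used
# instead: values at or below the batch median are scaled by M_i/M_ij, values
# above it are mapped affinely onto (M_i, 1]. The map is non-decreasing,
# fixes 0 and 1, and sends the batch median exactly to the pooled median.
#
# Copy-number log2 ratios are measured against a normal-DNA co-hybridisation
# on the same array and are not batch-corrected; the pipeline enforces this.

row_medians <- function(m) apply(m, 1L, stats::median, na.rm = TRUE)

row_scales <- function(m, estimator = c("sd", "mad")) {
  estimator <- match.arg(estimator)
  if (estimator == "mad") return(apply(m, 1L, stats::mad, na.rm = TRUE))
  nobs <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums(m * m, na.rm = TRUE) - nobs * mu^2
  out <- sqrt(pmax(ss, 0) / (nobs - 1L))
  out[nobs < 2L] <- NA_real_
  out
}

check_batches <- function(m, batches) {
  sid <- sample_ids(m)
  if (!is.null(names(batches))) {
    if (!all(sid %in% names(batches)))
      stop("every sample needs a batch label")
    batches <- batches[sid]
  } else if (length(batches) != length(sid)) {
    stop("batches must be named by sample id or match the column count")
  }
  batches <- as.character(batches)
  if (anyNA(batches)) stop("missing batch labels")
  small <- names(which(table(batches) < 25L))
  if (length(small))
    warning(sprintf("batch(es) with fewer than 25 samples: %s",
                    paste(small, collapse = ", ")),
            call. = FALSE)
  batches
}

new_batch_report <- function(rows, modality, estimator = NA_character_) {
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  structure(list(table = rep, modality = modality,
                 scale_estimator = estimator),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  tab <- x$table
  cat(sprintf("batch_report [%s]: %d features x %d batches\n", x$modality,
              length(unique(tab$feature_id)), length(unique(tab$batch))))
  flagged <- tab$flag != ""
  if (any(flagged))
    cat(sprintf("  flagged feature/batch cells: %d\n", sum(flagged)))
  invisible(x)
}

#' Location/scale batch correction for log2 expression
#'
#' Adjusts every feature within every batch so that the batch median equals
#' the pooled per-feature median and the batch scale equals the pooled scale.
#' Statistics are computed on observed (non-missing) entries only; missing
#' entries stay missing. A batch with zero (or undefined) within-batch scale
#' for a feature carries no spread information: its values are set to the
#' pooled median and flagged. Batches of size one are passed through
#' unadjusted with a warning. A warning is also raised for batches with
#' fewer than 25 samples, where L/S estimates get noisy.
#'
#' @param m An `omics_matrix` with modality `"expression"` (any continuous
#'   unbounded modality is accepted except copy number, which must not be
#'   batch-corrected).
#' @param batches Batch label per sample: either a vector named by sample id
#'   or a vector aligned with the matrix columns.
#' @param scale_estimator `"sd"` (default) or `"mad"` (median absolute
#'   deviation, consistency constant 1.4826).
#' @return List with `matrix` (the adjusted `omics_matrix`) and `report`
#'   (a `"batch_report"`: per feature/batch pre/post medians and scales,
#'   batch sizes, flags).
#' @export
correct_expression <- function(m, batches, scale_estimator = c("sd", "mad")) {
  scale_estimator <- match.arg(scale_estimator)
  if (m$modality == "copy_number")
    stop("copy-number matrices are not batch-corrected")
  batches <- check_batches(m, batches)
  v <- m$values
  gm <- row_medians(v)
  gs <- row_scales(v, scale_estimator)
  out <- v
  rows <- list()
  for (b in unique(batches)) {
    cols <- which(batches == b)
    sub <- v[, cols, drop = FALSE]
    flag <- rep("", nrow(v))
    if (length(cols) == 1L) {
      warning(sprintf("batch '%s' has a single sample; passed through unadjusted", b),
              call. = FALSE)
      bm <- sub[, 1L]
      bs <- rep(NA_real_, nrow(v))
      adj <- sub
      flag[] <- "size1"
    } else {
      bm <- row_medians(sub)
      bs <- row_scales(sub, scale_estimator)
      ratio <- gs / bs
      degen <- is.na(bs) | bs == 0
      ratio[degen] <- 0          # no within-batch spread: collapse to M_i
      ratio[gs == 0] <- 0
      adj <- sweep(sweep(sub, 1L, bm, "-"), 1L, ratio, "*") + gm
      flag[degen] <- "zero_scale"
    }
    out[, cols] <- adj
    rows[[b]] <- data.frame(
      feature_id = rownames(v), batch = b, n = length(cols),
      pre_median = bm, post_median = row_medians(adj),
      pre_scale = bs, post_scale = row_scales(adj, scale_estimator),
      flag = flag, stringsAsFactors = FALSE)
  }
  list(matrix = omics_matrix(out, m$modality, m$annotations),
       report = new_batch_report(rows, m$modality, scale_estimator))
}

# Piecewise-linear beta map for one feature/batch: pins 0 -> 0, M_ij -> M_i,
# 1 -> 1; non-decreasing on [0, 1].
beta_map <- function(b, m_global, m_batch) {
  if (is.na(m_batch) || is.na(m_global)) return(b)
  lo <- !is.na(b) & b <= m_batch
  hi <- !is.na(b) & b > m_batch
  out <- b
  if (m_batch > 0) out[lo] <- b[lo] * m_global / m_batch
  if (m_batch < 1) out[hi] <- m_global +
      (b[hi] - m_batch) * (1 - m_global) / (1 - m_batch)
  pmin(pmax(out, 0), 1)
}

#' Bounded rescaling batch correction for methylation beta values
#'
#' Applies, per feature and batch, the piecewise-linear map that scales
#' values below the batch median by `M_i / M_ij` and maps values above it
#' affinely onto `(M_i, 1]`, so batch medians align to the pooled median
#' while the \[0, 1\] range and monotonicity are preserved. Degenerate batch
#' medians (0: no lower rescaling possible; 1: no upper branch) leave the
#' corresponding branch untouched and are flagged.
#'
#' @param m An `omics_matrix` with modality `"methylation"`.
#' @inheritParams correct_expression
#' @return List with `matrix` and `report`, as [correct_expression()].
#' @export
correct_methylation <- function(m, batches) {
  if (m$modality != "methylation")
    stop("correct_methylation requires a methylation matrix")
  batches <- check_batches(m, batches)
  v <- m$values
  gm <- row_medians(v)
  out <- v
  rows <- list()
  for (b in unique(batches)) {
    cols <- which(batches == b)
    sub <- v[, cols, drop = FALSE]
    bm <- if (length(cols) == 1L) sub[, 1L] else row_medians(sub)
    flag <- rep("", nrow(v))
    if (length(cols) == 1L) {
      warning(sprintf("batch '%s' has a single sample; passed through unadjusted", b),
              call. = FALSE)
      adj <- sub
      flag[] <- "size1"
    } else {
      adj <- sub
      for (i in seq_len(nrow(sub))) adj[i, ] <- beta_map(sub[i, ], gm[i], bm[i])
      flag[!is.na(bm) & bm == 0] <- "median_zero"
      flag[!is.na(bm) & bm == 1] <- "median_one"
    }
    out[, cols] <- adj
    rows[[b]] <- data.frame(
      feature_id = rownames(v), batch = b, n = length(cols),
      pre_median = bm, post_median = row_medians(adj),
      pre_scale = NA_real_, post_scale = NA_real_,
      flag = flag, stringsAsFactors = FALSE)
  }
  list(matrix = omics_matrix(out, "methylation", m$annotations),
       report = new_batch_report(rows, "methylation"))
}
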