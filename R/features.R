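# Survival-driven feature selection: status categorization, log-rank scan,
# and the confounder / fold-change refinement funnels.

#' Thresholds governing the feature-selection funnel
#'
#' Defaults: copy-number gain above 0.4 and loss below -0.5 (log2 ratio),
#' methylation hyper/hypo cutoffs at the per-feature 0.75/0.25 quantiles,
#' scan level 0.05, minimum tested-group size max(ceil(0.15 n), 13),
#' confounder-test level 0.05, age Spearman cutoff 0.5, and a 1.3x
#' expression fold-change concordance requirement.
#'
#' @param cn_gain,cn_loss Copy-number log2-ratio cutoffs; a value is a gain
#'   when strictly above `cn_gain`, a loss when strictly below `cn_loss`.
#' @param meth_hi_quantile,meth_lo_quantile Per-feature beta quantiles
#'   bounding hyper/normal/hypo methylation.
#' @param scan_alpha Log-rank selection level.
#' @param min_group_frac,min_group_n A contrast is tested only when both
#'   groups have at least `max(ceiling(min_group_frac * n), min_group_n)`
#'   samples (the two readings coincide at n = 85).
#' @param confounder_alpha Level for the age/stage refinement tests.
#' @param age_spearman_cut Absolute Spearman correlation with age above
#'   which a methylation feature is treated as age-confounded.
#' @param fc_cut Minimum expression fold change (linear scale) between the
#'   tested groups; boundary inclusive.
#' @return A list of class `"feature_thresholds"`.
#' @export
feature_thresholds <- function(cn_gain = 0.4, cn_loss = -0.5,
                               meth_hi_quantile = 0.75,
                               meth_lo_quantile = 0.25,
                               scan_alpha = 0.05,
                               min_group_frac = 0.15, min_group_n = 13L,
                               confounder_alpha = 0.05,
                               age_spearman_cut = 0.5,
                               fc_cut = 1.3) {
  stopifnot(cn_loss < cn_gain,
            meth_lo_quantile > 0, meth_lo_quantile < meth_hi_quantile,
            meth_hi_quantile < 1, fc_cut > 1)
  structure(list(cn_gain = cn_gain, cn_loss = cn_loss,
                 meth_hi_quantile = meth_hi_quantile,
                 meth_lo_quantile = meth_lo_quantile,
                 scan_alpha = scan_alpha,
                 min_group_frac = min_group_frac,
                 min_group_n = as.integer(min_group_n),
                 confounder_alpha = confounder_alpha,
                 age_spearman_cut = age_spearman_cut,
                 fc_cut = fc_cut),
            class = "feature_thresholds")
}

#' Minimum admissible tested-group size
#'
#' Both log-rank groups must hold at least `max(ceiling(frac * n), min_n)`
#' samples; with the defaults and a cohort of 85 this is 13.
#'
#' @param n Cohort size.
#' @param thr A `feature_thresholds` object.
#' @return Integer minimum group size.
#' @export
min_group_size <- function(n, thr = feature_thresholds()) {
  max(as.integer(ceiling(thr$min_group_frac * n)), thr$min_group_n)
}

#' Categorize copy-number log2 ratios into gain/normal/loss
#'
#' `gain` strictly above `cn_gain` (default 0.4), `loss` strictly below
#' `cn_loss` (default -0.5), `normal` in between (boundaries inclusive);
#' missing stays missing.
#'
#' @param m Copy-number `omics_matrix`.
#' @param thr A `feature_thresholds` object.
#' @return Character matrix over `"gain"`, `"normal"`, `"loss"`, `NA`.
#' @export
categorize_cn <- function(m, thr = feature_thresholds()) {
  v <- m$values
  out <- matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  out[!is.na(v) & v > thr$cn_gain] <- "gain"
  out[!is.na(v) & v < thr$cn_loss] <- "loss"
  out[!is.na(v) & v >= thr$cn_loss & v <= thr$cn_gain] <- "normal"
  out
}

#' Categorize beta values into hyper/mid/hypo methylation
#'
#' Cutoffs are per-feature empirical quantiles (linear interpolation) of the
#' non-missing batch-corrected beta values: `hyper` strictly above the 0.75
#' quantile, `hypo` strictly below the 0.25 quantile, `mid` in between
#' (boundaries inclusive). The numeric cutoffs are returned so that held-out
#' samples can be categorized with the same criterion.
#'
#' @param m Methylation `omics_matrix` (batch-corrected).
#' @param thr A `feature_thresholds` object.
#' @param cutoffs Optional data frame (`feature_id`, `lo`, `hi`) of stored
#'   cutoffs to reuse instead of recomputing (e.g. training-derived cutoffs
#'   applied to a testing cohort).
#' @return List with `status` (character matrix over `"hyper"`, `"mid"`,
#'   `"hypo"`, `NA`) and `cutoffs` (data frame `feature_id`, `lo`, `hi`).
#' @export
categorize_meth <- function(m, thr = feature_thresholds(), cutoffs = NULL) {
  v <- m$values
  if (is.null(cutoffs)) {
    qs <- t(apply(v, 1L, stats::quantile,
                  probs = c(thr$meth_lo_quantile, thr$meth_hi_quantile),
                  na.rm = TRUE, names = FALSE))
    cutoffs <- data.frame(feature_id = rownames(v),
                          lo = qs[, 1L], hi = qs[, 2L],
                          stringsAsFactors = FALSE)
    rownames(cutoffs) <- NULL
  } else {
    if (!all(rownames(v) %in% cutoffs$feature_id))
      stop("stored cutoffs missing for some features")
    cutoffs <- cutoffs[match(rownames(v), cutoffs$feature_id), , drop = FALSE]
  }
  lo <- cutoffs$lo; hi <- cutoffs$hi
  out <- matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  out[!is.na(v) & v > hi] <- "hyper"
  out[!is.na(v) & v < lo] <- "hypo"
  out[!is.na(v) & v >= lo & v <= hi] <- "mid"
  list(status = out, cutoffs = cutoffs)
}

contrast_groups <- function(contrast) {
  switch(contrast,
         gain_vs_normal = list(alt = "gain", ref = "normal", zero = "loss"),
         loss_vs_normal = list(alt = "loss", ref = "normal", zero = "gain"),
         hyper_vs_rest = list(alt = "hyper", ref = c("mid", "hypo"), zero = character()),
         hypo_vs_rest = list(alt = "hypo", ref = c("mid", "hyper"), zero = character()),
         stop("unknown contrast: ", contrast))
}

default_contrasts <- function(modality) {
  switch(modality,
         copy_number = c("gain_vs_normal", "loss_vs_normal"),
         methylation = c("hyper_vs_rest", "hypo_vs_rest"),
         stop("no survival contrasts for modality ", modality))
}

#' Scan features for survival-associated status contrasts
#'
#' For every feature and contrast (copy number: gain vs normal and loss vs
#' normal; methylation: hyper vs non-hyper and hypo vs non-hypo), runs a
#' two-group log-rank test on PFS provided both groups reach the minimum
#' group size, and keeps contrasts with p below `scan_alpha`. Each kept test
#' records the two group memberships and which group survives longer
#' (`"group1"` = the altered-status group named first in the contrast).
#'
#' @param status Character status matrix from [categorize_cn()] or
#'   [categorize_meth()].
#' @param pfs PFS data frame from [derive_pfs()], restricted to the scanned
#'   cohort; its samples must all appear in `status`.
#' @param modality `"copy_number"` or `"methylation"`.
#' @param thr A `feature_thresholds` object.
#' @param contrasts Contrasts to scan (defaults per modality).
#' @param keep_all Keep tests regardless of the p-value gate (group-size
#'   gate still applies); used for diagnostics.
#' @return An object of class `"feature_tests"`: a list of test records,
#'   each with `feature_id`, `modality`, `contrast`, `p_value`, `direction`
#'   (`"group1"`/`"group2"`, the longer-survival side), `group1`/`group2`
#'   sample ids and `flags`. `as.data.frame()` gives a summary table.
#' @export
scan_features <- function(status, pfs, modality, thr = feature_thresholds(),
                          contrasts = default_contrasts(modality),
                          keep_all = FALSE) {
  ids <- pfs$sample_id
  if (!all(ids %in% colnames(status)))
    stop("status matrix missing scanned samples")
  status <- status[, ids, drop = FALSE]
  tmin <- min_group_size(length(ids), thr)
  time <- pfs$time; event <- pfs$event
  tests <- list()
  for (f in seq_len(nrow(status))) {
    row <- status[f, ]
    for (ctr in contrasts) {
      cg <- contrast_groups(ctr)
      i1 <- which(row %in% cg$alt)
      i2 <- which(row %in% cg$ref)
      if (length(i1) < tmin || length(i2) < tmin) next
      lr <- tryCatch(logrank_test(time[i1], event[i1], time[i2], event[i2]),
                     error = function(e) NULL)
      if (is.null(lr)) next
      if (!keep_all && lr$p_value >= thr$scan_alpha) next
      tests[[length(tests) + 1L]] <- list(
        feature_id = rownames(status)[f], modality = modality,
        contrast = ctr, p_value = lr$p_value,
        direction = if (is.na(lr$direction)) NA_character_
                    else c(a = "group1", b = "group2")[[lr$direction]],
        group1 = ids[i1], group2 = ids[i2], flags = character())
    }
  }
  structure(tests, class = "feature_tests")
}

#' @export
as.data.frame.feature_tests <- function(x, ...) {
  if (!length(x))
    return(data.frame(feature_id = character(), modality = character(),
                      contrast = character(), p_value = numeric(),
                      direction = character(), n1 = integer(),
                      n2 = integer(), flags = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    feature_id = vapply(x, `[[`, character(1L), "feature_id"),
    modality = vapply(x, `[[`, character(1L), "modality"),
    contrast = vapply(x, `[[`, character(1L), "contrast"),
    p_value = vapply(x, `[[`, numeric(1L), "p_value"),
    direction = vapply(x, `[[`, character(1L), "direction"),
    n1 = vapply(x, function(t) length(t$group1), integer(1L)),
    n2 = vapply(x, function(t) length(t$group2), integer(1L)),
    flags = vapply(x, function(t) paste(t$flags, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
}

#' @export
print.feature_tests <- function(x, ...) {
  cat(sprintf("feature_tests: %d selected feature/contrast tests\n", length(x)))
  if (length(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Remove features confounded by age or tumor stage
#'
#' Copy number: a test is dropped when the ages of its two groups differ
#' (Wilcoxon rank-sum p below `confounder_alpha`) or when stage III/IV
#' assignment is unbalanced between the groups (Fisher exact p below
#' `confounder_alpha`). Methylation: a feature is dropped when its beta
#' values correlate with age (|Spearman| above `age_spearman_cut`) or differ
#' between stage III and stage IV samples (Wilcoxon p below
#' `confounder_alpha`). Dropped tests are kept, flagged, in the `dropped`
#' attribute.
#'
#' @param tests A `feature_tests` object carrying group memberships.
#' @param clinical A `clinical_table` covering the tested samples.
#' @param thr A `feature_thresholds` object.
#' @param beta Methylation `omics_matrix` (required for methylation tests).
#' @return Filtered `feature_tests`; attribute `dropped` holds the flagged
#'   removals.
#' @export
refine_confounders <- function(tests, clinical, thr = feature_thresholds(),
                               beta = NULL) {
  s <- clinical$samples
  age <- stats::setNames(s$age, s$sample_id)
  stage <- stats::setNames(s$stage, s$sample_id)
  kept <- list()
  dropped <- list()
  for (t in tests) {
    flags <- character()
    if (t$modality == "copy_number") {
      if (wilcoxon_ranksum(age[t$group1], age[t$group2]) < thr$confounder_alpha)
        flags <- c(flags, "age_confounded")
      tab <- rbind(g1 = c(sum(stage[t$group1] == "III"), sum(stage[t$group1] == "IV")),
                   g2 = c(sum(stage[t$group2] == "III"), sum(stage[t$group2] == "IV")))
      if (fisher_exact_2x2(tab) < thr$confounder_alpha)
        flags <- c(flags, "stage_confounded")
    } else {
      if (is.null(beta))
        stop("refine_confounders needs the beta matrix for methylation tests")
      ids <- c(t$group1, t$group2)
      bv <- beta$values[t$feature_id, ids]
      rho <- tryCatch(suppressWarnings(spearman_cor(bv, age[ids])),
                      error = function(e) 0)
      if (abs(rho) > thr$age_spearman_cut)
        flags <- c(flags, "age_confounded")
      b3 <- bv[stage[ids] == "III"]
      b4 <- bv[stage[ids] == "IV"]
      if (length(b3) && length(b4) &&
          wilcoxon_ranksum(b3, b4) < thr$confounder_alpha)
        flags <- c(flags, "stage_confounded")
    }
    if (length(flags)) {
      t$flags <- c(t$flags, flags)
      dropped[[length(dropped) + 1L]] <- t
    } else {
      kept[[length(kept) + 1L]] <- t
    }
  }
  structure(kept, class = "feature_tests",
            dropped = structure(dropped, class = "feature_tests"))
}

#' Keep features whose groups differ in expression fold change
#'
#' Concordance filter: a test survives when the mean log2 expression of its
#' gene differs between the two tested groups by at least `log2(fc_cut)`
#' (boundary inclusive, evaluated with a 1e-12 tolerance). Copy-number
#' features are their own genes; methylation features are mapped through
#' `feature_gene_map`. Features without a mapped gene present in the
#' expression matrix are dropped and flagged `no_expression`.
#'
#' @param tests A `feature_tests` object.
#' @param expression Batch-corrected expression `omics_matrix`.
#' @param thr A `feature_thresholds` object.
#' @param feature_gene_map Named character vector mapping feature ids (e.g.
#'   CpG ids) to gene symbols; unnecessary when features are genes.
#' @return Filtered `feature_tests`; attribute `dropped` as in
#'   [refine_confounders()].
#' @export
refine_foldchange <- function(tests, expression, thr = feature_thresholds(),
                              feature_gene_map = NULL) {
  ev <- expression$values
  log_cut <- log2(thr$fc_cut) - 1e-12
  kept <- list()
  dropped <- list()
  for (t in tests) {
    gene <- t$feature_id
    if (!is.null(feature_gene_map) && t$feature_id %in% names(feature_gene_map))
      gene <- feature_gene_map[[t$feature_id]]
    if (is.na(gene) || !(gene %in% rownames(ev))) {
      t$flags <- c(t$flags, "no_expression")
      dropped[[length(dropped) + 1L]] <- t
      next
    }
    m1 <- mean(ev[gene, intersect(t$group1, colnames(ev))], na.rm = TRUE)
    m2 <- mean(ev[gene, intersect(t$group2, colnames(ev))], na.rm = TRUE)
    if (is.nan(m1) || is.nan(m2) || abs(m1 - m2) < log_cut) {
      t$flags <- c(t$flags, "fc_failed")
      dropped[[length(dropped) + 1L]] <- t
    } else {
      kept[[length(kept) + 1L]] <- t
    }
  }
  structure(kept, class = "feature_tests",
            dropped = structure(dropped, class = "feature_tests"))
}
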