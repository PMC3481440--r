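# The fitting interface: chemoclust() runs the full training procedure --
# batch correction, sample selection, per-modality feature selection,
# F-score discretization, Jaccard/complete-linkage clustering and the
# integration into a PPT/GPT classification -- and predict() carries the
# weighted-KNN justification onto the held-out testing cohort.

count_features <- function(tests) length(unique(vapply(tests, `[[`,
                                                       character(1L),
                                                       "feature_id")))

fit_modality <- function(status, pfs, modality, clinical, expression, thr,
                         beta = NULL, feature_gene_map = NULL, alpha = 0.05) {
  scanned <- scan_features(status, pfs, modality, thr)
  refined <- refine_confounders(scanned, clinical, thr, beta = beta)
  final <- refine_foldchange(refined, expression, thr,
                             feature_gene_map = feature_gene_map)
  fsc <- assign_fscores(final, status[, pfs$sample_id, drop = FALSE])
  clusters <- cluster_samples(fsc, pfs, alpha = alpha)
  list(tests = final, fscores = fsc, clusters = clusters,
       funnel = c(scanned = count_features(scanned),
                  after_confounders = count_features(refined),
                  after_foldchange = count_features(final)))
}

#' Fit the confounder-reduced chemotherapy-response classification
#'
#' Runs the full training procedure on a multi-omics cohort: location/scale
#' batch correction of expression and methylation (copy number is never
#' corrected), derivation of progression-free survival, rule-based selection
#' of uniformly treated training and testing cohorts, survival-driven
#' feature selection with age/stage confounder and expression fold-change
#' refinement, F-score discretization, Jaccard/complete-linkage clustering
#' into poor (PPT) and good (GPT) prognosis tumors per modality, and the
#' integration of the two classifications. Weighted-KNN models for
#' classifying held-out samples are stored on the fit; use [predict()] for
#' the testing cohort.
#'
#' @param expression Expression `omics_matrix` (log2).
#' @param copy_number Gene-level copy-number `omics_matrix` (log2 ratios).
#' @param methylation Methylation `omics_matrix` (beta values).
#' @param clinical A `clinical_table` covering the samples.
#' @param rules A [selection_rules()] object.
#' @param thresholds A [feature_thresholds()] object.
#' @param k Neighbor count for the stored KNN models.
#' @param scale_estimator Scale estimator for expression batch correction.
#' @param correct_batches Apply batch correction (disable only for data
#'   corrected upstream).
#' @param alpha Proposal level for the between-cluster log-rank tests.
#' @return An object of class `"chemoclust"`; see [summary.chemoclust()]
#'   for the funnel report and [predict.chemoclust()] for test-cohort
#'   classification.
#' @export
chemoclust <- function(expression, copy_number, methylation, clinical,
                       rules = selection_rules(),
                       thresholds = feature_thresholds(),
                       k = 3L, scale_estimator = c("sd", "mad"),
                       correct_batches = TRUE, alpha = 0.05) {
  scale_estimator <- match.arg(scale_estimator)
  stopifnot(expression$modality == "expression",
            copy_number$modality == "copy_number",
            methylation$modality == "methylation")
  batches <- stats::setNames(clinical$samples$batch, clinical$samples$sample_id)
  batch_reports <- list()
  if (correct_batches) {
    ce <- correct_expression(expression,
                             batches[intersect(names(batches), sample_ids(expression))],
                             scale_estimator)
    expression <- ce$matrix
    cm <- correct_methylation(methylation,
                              batches[intersect(names(batches), sample_ids(methylation))])
    methylation <- cm$matrix
    batch_reports <- list(expression = ce$report, methylation = cm$report)
  }

  common <- align_samples(list(expression, copy_number, methylation), clinical)
  expression <- subset_samples(expression, common)
  copy_number <- subset_samples(copy_number, common)
  methylation <- subset_samples(methylation, common)
  cl_samples <- clinical$samples[clinical$samples$sample_id %in% common, , drop = FALSE]
  cl_trt <- clinical$treatments[clinical$treatments$sample_id %in% common, , drop = FALSE]
  clinical <- clinical_table(cl_samples, cl_trt)

  pfs <- derive_pfs(clinical)
  cohorts <- assign_cohorts(clinical, rules)
  train <- cohorts$training
  if (length(train) < 4L) stop("training cohort too small to cluster")
  pfs_train <- pfs[match(train, pfs$sample_id), , drop = FALSE]

  expr_train <- subset_samples(expression, train)
  cn_train <- subset_samples(copy_number, train)
  meth_train <- subset_samples(methylation, train)

  cn_status <- categorize_cn(cn_train, thresholds)
  cn_fit <- fit_modality(cn_status, pfs_train, "copy_number", clinical,
                         expr_train, thresholds, alpha = alpha)

  meth_cat <- categorize_meth(meth_train, thresholds)
  cpg_map <- NULL
  ann <- methylation$annotations
  if (!is.null(ann) && "gene_symbol" %in% names(ann))
    cpg_map <- stats::setNames(ann$gene_symbol, ann$feature_id)
  meth_fit <- fit_modality(meth_cat$status, pfs_train, "methylation", clinical,
                           expr_train, thresholds, beta = meth_train,
                           feature_gene_map = cpg_map, alpha = alpha)

  training_class <- integrate_classifications(cn_fit$clusters,
                                              meth_fit$clusters,
                                              pfs_train, alpha = alpha)

  models <- list(
    copy_number = if (nrow(cn_fit$fscores$scores) > 0L)
      knn_model(cn_fit$fscores, cn_fit$clusters, cn_fit$tests, thresholds,
                "copy_number", k = min(k, length(train))),
    methylation = if (nrow(meth_fit$fscores$scores) > 0L)
      knn_model(meth_fit$fscores, meth_fit$clusters, meth_fit$tests,
                thresholds, "methylation", k = min(k, length(train)),
                meth_cutoffs = meth_cat$cutoffs))

  structure(list(
    expression = expression, copy_number = copy_number,
    methylation = methylation, clinical = clinical,
    pfs = pfs, cohorts = cohorts,
    cn = cn_fit, meth = meth_fit,
    training_class = training_class,
    models = models,
    batch_reports = batch_reports,
    rules = rules, thresholds = thresholds, alpha = alpha, k = k,
    call = match.call()), class = "chemoclust")
}

#' @export
print.chemoclust <- function(x, ...) {
  cat("chemoclust fit\n")
  cat(sprintf("  samples: %d aligned; %d training / %d testing / %d excluded\n",
              nrow(x$clinical$samples), length(x$cohorts$training),
              length(x$cohorts$testing), nrow(x$cohorts$excluded)))
  cat(sprintf("  selected features: %d copy-number, %d methylation\n",
              nrow(x$cn$fscores$scores), nrow(x$meth$fscores$scores)))
  tc <- x$training_class
  cat(sprintf("  training classification: %d PPT / %d GPT, log-rank p = %.3g%s\n",
              length(tc$ppt_ids), length(tc$gpt_ids), tc$logrank_p,
              if (isTRUE(tc$proposed)) " (proposed)" else ""))
  invisible(x)
}

#' Funnel summary of a chemoclust fit
#'
#' Prints the sample-selection and feature-selection funnels, the cluster
#' sizes per modality, the integrated classification and the training
#' log-rank test.
#'
#' @param object A `chemoclust` fit.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.chemoclust <- function(object, ...) {
  x <- object
  ex <- x$cohorts$excluded
  cat("Sample selection\n")
  cat(sprintf("  %d samples with all three profiles\n", nrow(x$clinical$samples)))
  cat(sprintf("  %d eligible (stage + treatment rules): %d training, %d testing\n",
              length(x$cohorts$training) + length(x$cohorts$testing),
              length(x$cohorts$training), length(x$cohorts$testing)))
  if (nrow(ex)) {
    tab <- table(ex$reason)
    cat(sprintf("  %d excluded (%s)\n", nrow(ex),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  for (mod in c("cn", "meth")) {
    f <- x[[mod]]$funnel
    cat(sprintf("%s feature funnel\n",
                if (mod == "cn") "Copy-number" else "Methylation"))
    cat(sprintf("  %d survival-associated -> %d after confounder refinement -> %d after fold-change\n",
                f[["scanned"]], f[["after_confounders"]], f[["after_foldchange"]]))
    cl <- x[[mod]]$clusters
    cat(sprintf("  clusters: %d PPT / %d GPT (log-rank p = %.3g)\n",
                length(cl$ppt_ids), length(cl$gpt_ids), cl$logrank_p))
  }
  tc <- x$training_class
  cat("Integrated training classification\n")
  cat(sprintf("  %d PPT (CN %d, methylation %d, overlap %d) vs %d GPT; log-rank p = %.3g%s\n",
              length(tc$ppt_ids), length(tc$cn_ppt_ids),
              length(tc$meth_ppt_ids), length(tc$overlap_ids),
              length(tc$gpt_ids), tc$logrank_p,
              if (isTRUE(tc$proposed)) " (proposed)" else ""))
  invisible(object)
}

#' Classify held-out samples with the stored weighted-KNN models
#'
#' Discretizes the samples with the training-derived features and cutoffs,
#' classifies them per modality with the weighted-KNN rule, takes the union
#' of the per-modality poor calls as the test PPT set, and tests the PFS
#' contrast by log-rank when survival is available.
#'
#' @param object A `chemoclust` fit.
#' @param copy_number,methylation Optional `omics_matrix` inputs for new
#'   samples; by default the fit's held-out testing cohort is classified.
#' @param pfs Optional PFS data frame for the new samples (defaults to the
#'   stored testing-cohort PFS).
#' @param ... Unused.
#' @return An object of class `"chemoclust_prediction"`: per-modality
#'   classification tables (`sample_id`, `p_f`, `label`), integrated
#'   `ppt_ids`/`gpt_ids`, and `logrank_p`.
#' @export
predict.chemoclust <- function(object, copy_number = NULL, methylation = NULL,
                               pfs = NULL, ...) {
  if (is.null(copy_number) && is.null(methylation)) {
    test <- object$cohorts$testing
    if (!length(test)) stop("no testing cohort stored and no new data supplied")
    copy_number <- subset_samples(object$copy_number, test)
    methylation <- subset_samples(object$methylation, test)
    if (is.null(pfs)) pfs <- object$pfs[match(test, object$pfs$sample_id), ]
  }
  per_mod <- list()
  poor <- list()
  universe <- character()
  for (mod in c("copy_number", "methylation")) {
    model <- object$models[[mod]]
    newdata <- if (mod == "copy_number") copy_number else methylation
    if (is.null(model) || is.null(newdata)) next
    f <- discretize_test(model, newdata)
    res <- classify_knn(model, f)
    per_mod[[mod]] <- res
    poor[[mod]] <- res$sample_id[res$label == "poor"]
    universe <- union(universe, res$sample_id)
  }
  ppt <- sort(unique(unlist(poor)))
  gpt <- sort(setdiff(universe, ppt))
  lp <- NA_real_
  if (!is.null(pfs) && length(ppt) && length(gpt)) {
    i1 <- match(ppt, pfs$sample_id)
    i2 <- match(gpt, pfs$sample_id)
    if (!anyNA(i1) && !anyNA(i2)) {
      lr <- tryCatch(logrank_test(pfs$time[i1], pfs$event[i1],
                                  pfs$time[i2], pfs$event[i2]),
                     error = function(e) NULL)
      if (!is.null(lr)) lp <- lr$p_value
    }
  }
  structure(list(per_modality = per_mod,
                 cn_ppt_ids = sort(poor$copy_number %||% character()),
                 meth_ppt_ids = sort(poor$methylation %||% character()),
                 ppt_ids = ppt, gpt_ids = gpt, logrank_p = lp),
            class = "chemoclust_prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chemoclust_prediction <- function(x, ...) {
  cat(sprintf("chemoclust_prediction: %d PPT (CN %d, methylation %d, overlap %d) / %d GPT\n",
              length(x$ppt_ids), length(x$cn_ppt_ids), length(x$meth_ppt_ids),
              length(intersect(x$cn_ppt_ids, x$meth_ppt_ids)),
              length(x$gpt_ids)))
  cat(sprintf("  PPT vs GPT log-rank p = %.4g\n", x$logrank_p))
  invisible(x)
}

#' Kaplan-Meier curves for the fitted classification
#'
#' Plots the product-limit PFS curves of the integrated PPT and GPT groups
#' of the training cohort (or of a prediction on the testing cohort).
#'
#' @param x A `chemoclust` fit.
#' @param prediction Optional `chemoclust_prediction` to plot instead of the
#'   training classification.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.chemoclust <- function(x, prediction = NULL, ...) {
  cls <- if (is.null(prediction)) x$training_class else prediction
  pfs <- x$pfs
  draw <- function(ids, col) {
    i <- match(ids, pfs$sample_id)
    km <- km_curve(pfs$time[i], pfs$event[i])
    graphics::lines(stats::stepfun(km$time, c(1, km$surv)), col = col,
                    do.points = FALSE, lwd = 2)
  }
  graphics::plot(NULL, xlim = c(0, max(pfs$time)), ylim = c(0, 1),
                 xlab = "Progression-free survival (days)",
                 ylab = "Survival probability", ...)
  if (length(cls$ppt_ids)) draw(cls$ppt_ids, "black")
  if (length(cls$gpt_ids)) draw(cls$gpt_ids, "grey60")
  graphics::legend("topright", lwd = 2, col = c("black", "grey60"),
                   legend = c(sprintf("PPT (n=%d)", length(cls$ppt_ids)),
                              sprintf("GPT (n=%d)", length(cls$gpt_ids))),
                   bty = "n")
  invisible(x)
}

#' Run the full pipeline on a (simulated or supplied) cohort
#'
#' Convenience orchestration: generate a synthetic cohort (or take one),
#' fit the training classification, classify the testing cohort, run the
#' two differential-expression comparisons (copy-number PPT vs GPT and
#' methylation PPT vs GPT), and collect a machine-readable run report.
#'
#' @param config A [sim_config()] used when `cohort` is `NULL`.
#' @param cohort Optionally a pre-built `synthetic_cohort` (or compatible
#'   list with the same elements).
#' @param ... Passed to [chemoclust()].
#' @return An object of class `"chemoclust_run"`: `fit`, `prediction`,
#'   `de_cn`, `de_meth`, `cohort` and `report` (nested list of funnel
#'   counts, cluster sizes, p-values and the configuration echo).
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL, ...) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  fit <- chemoclust(cohort$expression, cohort$copy_number,
                    cohort$methylation, cohort$clinical, ...)
  prediction <- if (length(fit$cohorts$testing) >= 2L)
    predict(fit) else NULL
  tc <- fit$training_class
  de_cn <- de_meth <- NULL
  if (length(tc$cn_ppt_ids) >= 2L && length(tc$gpt_ids) >= 2L)
    de_cn <- differential_expression(fit$expression, tc$cn_ppt_ids, tc$gpt_ids)
  if (length(tc$meth_ppt_ids) >= 2L && length(tc$gpt_ids) >= 2L)
    de_meth <- differential_expression(fit$expression, tc$meth_ppt_ids, tc$gpt_ids)
  report <- list(
    n_samples = nrow(fit$clinical$samples),
    n_training = length(fit$cohorts$training),
    n_testing = length(fit$cohorts$testing),
    n_excluded = nrow(fit$cohorts$excluded),
    cn_funnel = as.list(fit$cn$funnel),
    meth_funnel = as.list(fit$meth$funnel),
    training = list(
      cn_ppt = length(tc$cn_ppt_ids), meth_ppt = length(tc$meth_ppt_ids),
      overlap = length(tc$overlap_ids), ppt = length(tc$ppt_ids),
      gpt = length(tc$gpt_ids), logrank_p = tc$logrank_p,
      proposed = isTRUE(tc$proposed)),
    testing = if (!is.null(prediction)) list(
      cn_ppt = length(prediction$cn_ppt_ids),
      meth_ppt = length(prediction$meth_ppt_ids),
      ppt = length(prediction$ppt_ids), gpt = length(prediction$gpt_ids),
      logrank_p = prediction$logrank_p),
    de = list(cn_passing = if (!is.null(de_cn)) sum(de_cn$passes),
              meth_passing = if (!is.null(de_meth)) sum(de_meth$passes)),
    seed = if (inherits(cohort, "synthetic_cohort")) cohort$config$seed,
    version = as.character(utils::packageVersion("chemoclust")))
  structure(list(fit = fit, prediction = prediction, de_cn = de_cn,
                 de_meth = de_meth, cohort = cohort, report = report),
            class = "chemoclust_run")
}

#' @export
print.chemoclust_run <- function(x, ...) {
  summary(x$fit)
  if (!is.null(x$prediction)) print(x$prediction)
  de <- x$report$de
  if (!is.null(de$cn_passing))
    cat(sprintf("Differentially expressed genes: %d (CN-PPT vs GPT), %s (meth-PPT vs GPT)\n",
                de$cn_passing,
                if (is.null(de$meth_passing)) "NA" else de$meth_passing))
  invisible(x)
}
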