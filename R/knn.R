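# Weighted K-nearest-neighbor justification of the training classification
# on held-out samples, using the training-derived features, discretization
# criteria and cluster labels.

#' Build a weighted-KNN model from a training classification
#'
#' Stores everything needed to score and classify new samples with the
#' training criterion: the selected tests (feature, winning contrast,
#' survival direction), the numeric discretization cutoffs (fixed 0.4/-0.5
#' thresholds for copy number; the training cohort's per-feature beta
#' quantile cutoffs for methylation), the training F-score matrix and the
#' cluster labels (-1 = poor profile / PPT, +1 = good profile / GPT).
#'
#' @param fscores Training `fscore_matrix`.
#' @param clusters Training `cluster_result` over the same samples.
#' @param tests The post-refinement `feature_tests` behind `fscores`.
#' @param thr The `feature_thresholds` used in training.
#' @param k Number of neighbors (default 3).
#' @param meth_cutoffs For methylation models, the training cutoff table
#'   from [categorize_meth()].
#' @param modality `"copy_number"` or `"methylation"`.
#' @return An object of class `"knn_model"`.
#' @export
knn_model <- function(fscores, clusters, tests, thr, modality,
                      k = 3L, meth_cutoffs = NULL) {
  ids <- colnames(fscores$scores)
  k <- as.integer(k)
  if (k < 1L || k > length(ids))
    stop("k must be between 1 and the number of training samples")
  labels <- stats::setNames(ifelse(ids %in% clusters$ppt_ids, -1L, 1L), ids)
  structure(list(scores = fscores$scores, labels = labels,
                 provenance = fscores$provenance,
                 tests = tests, thr = thr, modality = modality,
                 k = k, meth_cutoffs = meth_cutoffs),
            class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("knn_model [%s]: %d features, %d training samples (%d poor / %d good), K = %d\n",
              x$modality, nrow(x$scores), length(x$labels),
              sum(x$labels == -1L), sum(x$labels == 1L), x$k))
  invisible(x)
}

#' Discretize held-out samples with training-derived criteria
#'
#' Categorizes the new samples' measurements using the cutoffs stored in
#' the model (copy-number thresholds; training beta quantiles) and maps the
#' statuses through the training contrasts/directions into F-scores, exactly
#' as in [assign_fscores()]. Model features missing from the new matrix get
#' an all-zero row with a warning.
#'
#' @param model A `knn_model`.
#' @param newdata An `omics_matrix` of the model's modality for the new
#'   samples.
#' @param recompute_meth_cutoffs Recompute beta quantile cutoffs on the new
#'   cohort instead of reusing the training cutoffs (sensitivity variant;
#'   default `FALSE` to avoid information leakage).
#' @return An `fscore_matrix` for the new samples.
#' @export
discretize_test <- function(model, newdata, recompute_meth_cutoffs = FALSE) {
  feats <- rownames(model$scores)
  v <- newdata$values
  missing_feats <- setdiff(feats, rownames(v))
  if (length(missing_feats)) {
    warning(sprintf("%d model feature(s) absent from new data; scored 0",
                    length(missing_feats)), call. = FALSE)
    pad <- matrix(NA_real_, length(missing_feats), ncol(v),
                  dimnames = list(missing_feats, colnames(v)))
    v <- rbind(v, pad)
  }
  v <- v[feats, , drop = FALSE]
  sub <- omics_matrix(v, newdata$modality, NULL)
  status <- if (model$modality == "methylation") {
    categorize_meth(sub, model$thr,
                    cutoffs = if (recompute_meth_cutoffs) NULL
                              else model$meth_cutoffs)$status
  } else {
    categorize_cn(sub, model$thr)
  }
  prov <- model$provenance
  scores <- matrix(0L, length(feats), ncol(v),
                   dimnames = list(feats, colnames(v)))
  for (i in seq_along(feats)) {
    p <- prov[prov$feature_id == feats[i], ]
    scores[i, ] <- score_from_status(status[feats[i], ], p$contrast[1L],
                                     p$direction[1L])
  }
  structure(list(scores = scores, provenance = prov),
            class = "fscore_matrix")
}

# Distance between a test profile and each training profile:
# d = max(#mismatch, 1) / #(informative in either); the max() keeps the
# inverse-distance weights finite for identical profiles. A pair with no
# informative position gets d = 1.
knn_distances <- function(f_test, train_scores) {
  m <- nrow(train_scores)
  num <- colSums(train_scores != f_test)
  den <- colSums(train_scores != 0L | f_test != 0L)
  d <- ifelse(den == 0L, 1, pmax(num, 1L) / den)
  d
}

#' Classify samples with the weighted-KNN discriminant
#'
#' For each sample, the K nearest training profiles (Jaccard-style distance
#' with a floor of one mismatch; ties broken by training sample id order)
#' vote with weights 1/d; the discriminant `P_f` is the weighted mean of
#' their labels, and the sample is called a good profile when `P_f > 0`,
#' poor otherwise (the boundary `P_f = 0` is poor).
#'
#' @param model A `knn_model`.
#' @param f An `fscore_matrix` of test profiles on the model's features
#'   (from [discretize_test()]).
#' @return Data frame with `sample_id`, `p_f` (in \[-1, 1\]) and `label`
#'   (`"poor"`/`"good"`).
#' @export
classify_knn <- function(model, f) {
  if (!identical(rownames(f$scores), rownames(model$scores)))
    stop("test F-scores must be on the model's features, in model order")
  train_ids <- colnames(model$scores)
  tie_order <- order(train_ids)
  out_pf <- numeric(ncol(f$scores))
  for (j in seq_len(ncol(f$scores))) {
    d <- knn_distances(f$scores[, j], model$scores)
    nn <- order(d[tie_order])[seq_len(model$k)]
    idx <- tie_order[nn]
    w <- 1 / d[idx]
    out_pf[j] <- sum(w * model$labels[idx]) / sum(w)
  }
  data.frame(sample_id = colnames(f$scores), p_f = out_pf,
             label = ifelse(out_pf > 0, "good", "poor"),
             stringsAsFactors = FALSE)
}
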