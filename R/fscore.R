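# Ternary F-score discretization, Jaccard distances, complete-linkage
# clustering and the integration of the per-modality classifications.
#
# The F-score encodes, per selected feature, whether a sample sits in the
# longer-survival (+1, favorable) or shorter-survival (-1, unfavorable)
# status group of the winning log-rank contrast; samples in the untested
# status (the loss group of a gain-vs-normal feature, say) or with missing
# measurements score 0 (unknown).

score_from_status <- function(status_row, contrast, direction) {
  cg <- contrast_groups(contrast)
  s_alt <- if (direction == "group1") 1L else -1L
  out <- integer(length(status_row))
  out[status_row %in% cg$alt] <- s_alt
  out[status_row %in% cg$ref] <- -s_alt
  out  # untested status and NA stay 0
}

#' Discretize selected features into F-scores
#'
#' Applies each post-refinement test's winning contrast and survival
#' direction to the status matrix: members of the longer-survival group get
#' +1, the shorter-survival group -1, and samples with the untested status
#' or missing values 0. A feature selected under both of its contrasts is
#' scored by the contrast with the smaller log-rank p-value. Tests whose
#' survival direction is undefined are dropped with a warning.
#'
#' @param tests A `feature_tests` object (post refinement).
#' @param status Status matrix covering the samples to score (its columns
#'   define the sample set; membership is re-derived from status so the same
#'   rules apply to held-out samples).
#' @return An object of class `"fscore_matrix"`: list with `scores`
#'   (feature-by-sample integer matrix over -1/0/+1) and `provenance`
#'   (per-feature winning contrast, p-value, direction).
#' @export
assign_fscores <- function(tests, status) {
  undef <- vapply(tests, function(t) is.na(t$direction), logical(1L))
  if (any(undef)) {
    warning(sprintf("%d feature(s) dropped: undefined survival direction",
                    sum(undef)), call. = FALSE)
    tests <- tests[!undef]
  }
  if (!length(tests)) {
    return(structure(list(scores = matrix(integer(), 0L, ncol(status),
                                          dimnames = list(NULL, colnames(status))),
                          provenance = data.frame(feature_id = character(),
                                                  contrast = character(),
                                                  p_value = numeric(),
                                                  direction = character(),
                                                  stringsAsFactors = FALSE)),
                     class = "fscore_matrix"))
  }
  df <- as.data.frame(structure(tests, class = "feature_tests"))
  # feature selected under two contrasts: keep the smaller p-value
  ord <- order(df$p_value)
  winners <- ord[!duplicated(df$feature_id[ord])]
  winners <- winners[order(match(df$feature_id[winners], rownames(status)))]
  scores <- matrix(0L, length(winners), ncol(status),
                   dimnames = list(df$feature_id[winners], colnames(status)))
  for (i in seq_along(winners)) {
    t <- tests[[winners[i]]]
    if (!t$feature_id %in% rownames(status))
      stop("status matrix missing feature ", t$feature_id)
    scores[i, ] <- score_from_status(status[t$feature_id, ], t$contrast,
                                     t$direction)
  }
  structure(list(scores = scores,
                 provenance = df[winners, c("feature_id", "contrast",
                                            "p_value", "direction")]),
            class = "fscore_matrix")
}

#' @export
print.fscore_matrix <- function(x, ...) {
  cat(sprintf("fscore_matrix: %d features x %d samples (favorable %d, unfavorable %d, unknown %d)\n",
              nrow(x$scores), ncol(x$scores), sum(x$scores == 1L),
              sum(x$scores == -1L), sum(x$scores == 0L)))
  invisible(x)
}

#' Jaccard-style distance between F-score profiles
#'
#' For samples k and k', the distance is the number of mismatching scores
#' divided by the number of positions where either sample is informative
#' (nonzero). A pair with no informative position in common is assigned
#' distance 1 and flagged. Distances lie in \[0, 1\] with zero
#' self-distance.
#'
#' @param f An `fscore_matrix` (or plain ternary matrix, features x samples)
#'   with at least 2 samples.
#' @return Symmetric distance matrix; attribute `uninformative_pairs` counts
#'   flagged pairs.
#' @export
jaccard_distance <- function(f) {
  s <- if (inherits(f, "fscore_matrix")) f$scores else as.matrix(f)
  if (ncol(s) < 2L) stop("jaccard_distance requires >= 2 samples")
  m <- nrow(s)
  pos <- s == 1L; zer <- s == 0L; neg <- s == -1L
  eq <- crossprod(pos) + crossprod(zer) + crossprod(neg)
  bothzero <- crossprod(zer)
  num <- m - eq            # mismatch count
  den <- m - bothzero      # positions informative in either sample
  d <- ifelse(den == 0L, 1, num / den)
  diag(d) <- 0
  dimnames(d) <- list(colnames(s), colnames(s))
  flagged <- sum(den == 0L & upper.tri(den))
  if (flagged > 0L)
    warning(sprintf("%d sample pair(s) share no informative feature; distance set to 1",
                    flagged), call. = FALSE)
  attr(d, "uninformative_pairs") <- flagged
  d
}

# Complete-linkage agglomeration with a deterministic tie-break: among pairs
# at the minimal height, merge the pair whose (sorted) smallest original
# member indices are lexicographically smallest. Returns the merge trace and
# the two clusters obtained by cutting before the final merge.
complete_linkage <- function(d) {
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  minmem <- seq_len(n)          # smallest original member index per cluster
  active <- rep(TRUE, n)
  work <- d
  diag(work) <- Inf
  work[!upper.tri(work) & !lower.tri(work)] <- Inf
  merges <- list()
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    keys <- cbind(pmin(minmem[idx[cand[, 1L]]], minmem[idx[cand[, 2L]]]),
                  pmax(minmem[idx[cand[, 1L]]], minmem[idx[cand[, 2L]]]))
    pick <- order(keys[, 1L], keys[, 2L])[1L]
    i <- idx[cand[pick, 1L]]; j <- idx[cand[pick, 2L]]
    merges[[step]] <- list(height = h,
                           left = members[[i]], right = members[[j]])
    members[[i]] <- c(members[[i]], members[[j]])
    minmem[i] <- min(minmem[i], minmem[j])
    active[j] <- FALSE
    # complete linkage: distance to the union is the max of the parts
    newd <- pmax(work[i, ], work[j, ])
    work[i, ] <- newd
    work[, i] <- newd
    work[i, i] <- Inf
  }
  last <- merges[[n - 1L]]
  list(merges = merges,
       heights = vapply(merges, `[[`, numeric(1L), "height"),
       cut2 = list(sort(last$left), sort(last$right)))
}

#' Cluster samples on F-score profiles and label PPT/GPT
#'
#' Agglomerative clustering with complete linkage on the Jaccard distance,
#' cut into exactly two clusters (or at the largest merge-height gap when
#' `cut = "gap"`). The cluster with the lower mean F-score -- the one
#' enriched with unfavorable scores -- is labelled PPT (poor prognosis
#' tumors), the other GPT. The PFS difference between the clusters is
#' tested by log-rank, and the classification is flagged `proposed` only
#' when p < 0.05.
#'
#' @param f An `fscore_matrix`.
#' @param pfs PFS data frame covering the clustered samples.
#' @param cut `"two"` (default) cuts into exactly 2 clusters; `"gap"` cuts
#'   at the largest gap in merge heights (exploratory).
#' @param alpha Proposal level for the between-cluster log-rank test.
#' @return An object of class `"cluster_result"`: `assignment` (named
#'   1/2 vector, 1 = PPT), `ppt_ids`, `gpt_ids`, `logrank_p`, `proposed`,
#'   `merges`, `heights`, `flags`, `mean_scores`.
#' @export
cluster_samples <- function(f, pfs, cut = c("two", "gap"), alpha = 0.05) {
  cut <- match.arg(cut)
  ids <- colnames(f$scores)
  flags <- character()
  if (nrow(f$scores) == 0L || ncol(f$scores) < 2L) {
    flags <- c(flags, "degenerate")
    return(structure(list(assignment = stats::setNames(rep(2L, length(ids)), ids),
                          ppt_ids = character(), gpt_ids = ids,
                          logrank_p = NA_real_, proposed = FALSE,
                          merges = NULL, heights = numeric(),
                          flags = flags, mean_scores = c(NA_real_, NA_real_)),
                     class = "cluster_result"))
  }
  d <- jaccard_distance(f)
  tree <- complete_linkage(d)
  if (cut == "two" || length(tree$heights) < 3L) {
    parts <- tree$cut2
  } else {
    gaps <- diff(tree$heights)
    k <- length(ids) - which.max(gaps)  # number of clusters after the gap
    parts <- cut_tree_k(tree, length(ids), max(2L, k))
    # label by lower mean score only supports 2 clusters; collapse to 2
    if (length(parts) > 2L) parts <- tree$cut2
  }
  mean_score <- vapply(parts, function(p) mean(f$scores[, p, drop = FALSE]),
                       numeric(1L))
  sizes <- lengths(parts)
  minid <- vapply(parts, min, numeric(1L))
  ord <- order(mean_score, sizes, minid)
  ppt <- parts[[ord[1L]]]
  gpt <- parts[[ord[2L]]]
  if (min(sizes) == 1L) flags <- c(flags, "singleton_cluster")
  lp <- NA_real_
  if (length(ppt) && length(gpt)) {
    i1 <- match(ids[ppt], pfs$sample_id)
    i2 <- match(ids[gpt], pfs$sample_id)
    lr <- tryCatch(logrank_test(pfs$time[i1], pfs$event[i1],
                                pfs$time[i2], pfs$event[i2]),
                   error = function(e) NULL)
    if (!is.null(lr)) lp <- lr$p_value else flags <- c(flags, "logrank_undefined")
  }
  if (identical(mean_score[ord[1L]], mean_score[ord[2L]]))
    flags <- c(flags, "score_tie")
  assignment <- stats::setNames(rep(2L, length(ids)), ids)
  assignment[ppt] <- 1L
  structure(list(assignment = assignment,
                 ppt_ids = ids[ppt], gpt_ids = ids[gpt],
                 logrank_p = lp,
                 proposed = isTRUE(lp < alpha),
                 merges = tree$merges, heights = tree$heights,
                 flags = flags,
                 mean_scores = mean_score[ord]),
            class = "cluster_result")
}

# cut a merge trace into k clusters (undo the last k-1 merges)
cut_tree_k <- function(tree, n, k) {
  parts <- lapply(seq_len(n), identity)
  alive <- rep(TRUE, n)
  for (m in tree$merges[seq_len(n - k)]) {
    i <- m$left[1L]
    parts[[i]] <- c(m$left, m$right)
    alive[setdiff(c(m$left, m$right), i)] <- FALSE
  }
  lapply(which(alive & lengths(parts) > 0), function(i) sort(parts[[i]]))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d PPT / %d GPT samples\n",
              length(x$ppt_ids), length(x$gpt_ids)))
  cat(sprintf("  between-cluster log-rank p = %.4g%s\n", x$logrank_p,
              if (isTRUE(x$proposed)) " (classification proposed)" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Integrate copy-number and methylation classifications
#'
#' The final poor-prognosis set is the union of the per-modality PPT
#' clusters; every other sample is a good-prognosis tumor. The PFS contrast
#' between the integrated groups is tested by log-rank.
#'
#' @param cn,meth `cluster_result` objects over the same sample universe
#'   (either may be `NULL` when a modality produced no classification).
#' @param pfs PFS data frame covering the samples.
#' @param alpha Proposal level.
#' @return An object of class `"ppt_classification"`: `ppt_ids`, `gpt_ids`,
#'   `overlap_ids`, `logrank_p`, `proposed`.
#' @export
integrate_classifications <- function(cn, meth, pfs, alpha = 0.05) {
  universe <- sort(unique(c(if (!is.null(cn)) names(cn$assignment),
                            if (!is.null(meth)) names(meth$assignment))))
  cn_ppt <- if (is.null(cn)) character() else cn$ppt_ids
  meth_ppt <- if (is.null(meth)) character() else meth$ppt_ids
  ppt <- sort(union(cn_ppt, meth_ppt))
  gpt <- setdiff(universe, ppt)
  lp <- NA_real_
  if (length(ppt) && length(gpt)) {
    i1 <- match(ppt, pfs$sample_id)
    i2 <- match(gpt, pfs$sample_id)
    lr <- tryCatch(logrank_test(pfs$time[i1], pfs$event[i1],
                                pfs$time[i2], pfs$event[i2]),
                   error = function(e) NULL)
    if (!is.null(lr)) lp <- lr$p_value
  }
  structure(list(ppt_ids = ppt, gpt_ids = gpt,
                 overlap_ids = sort(intersect(cn_ppt, meth_ppt)),
                 cn_ppt_ids = sort(cn_ppt), meth_ppt_ids = sort(meth_ppt),
                 logrank_p = lp, proposed = isTRUE(lp < alpha)),
            class = "ppt_classification")
}

#' @export
print.ppt_classification <- function(x, ...) {
  cat(sprintf("ppt_classification: %d PPT (CN %d, methylation %d, overlap %d), %d GPT\n",
              length(x$ppt_ids), length(x$cn_ppt_ids), length(x$meth_ppt_ids),
              length(x$overlap_ids), length(x$gpt_ids)))
  cat(sprintf("  PPT vs GPT log-rank p = %.4g%s\n", x$logrank_p,
              if (isTRUE(x$proposed)) " (proposed)" else ""))
  invisible(x)
}
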