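# Statistical primitives used by the survival feature scan and refinements.
#
# The two-group log-rank test and the Kaplan-Meier estimator are implemented
# here directly: the scan needs the per-group observed/expected event counts
# to orient the ternary F-scores (which group survives longer), and the
# feature-by-feature scan makes this the hot loop of the whole procedure.
# The remaining primitives (Wilcoxon rank-sum, Fisher exact, Spearman,
# two-sample t) delegate to the corresponding stats:: routines with the edge
# cases the pipeline relies on (zero margins, constant vectors) pinned down.

#' Two-group log-rank test with survival direction
#'
#' Standard two-group log-rank chi-square (1 df) with the hypergeometric
#' variance at tied event times. Beyond the p-value, the result records which
#' group has fewer observed than expected events: that group is labelled the
#' longer-survival group, the quantity the F-score discretization needs.
#'
#' @param time_a,event_a Follow-up times (days) and event indicators
#'   (`TRUE` = failure observed, `FALSE` = censored) for group A.
#' @param time_b,event_b Same for group B.
#' @return A list of class `"logrank_test"` with elements `chisq`, `p_value`,
#'   `observed` and `expected` (length-2, groups A and B), `direction`
#'   (`"a"` or `"b"` for the longer-survival group, `NA` if undefined) and
#'   `n` (group sizes).
#' @examples
#' lr <- logrank_test(c(5, 8, 12), c(TRUE, TRUE, FALSE),
#'                    c(20, 25, 30), c(TRUE, FALSE, TRUE))
#' lr$direction  # "b": fewer events than expected in group B
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop("log-rank test requires two non-empty groups")
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b))
  time <- c(time_a, time_b)
  event <- as.logical(c(event_a, event_b))
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  if (anyNA(time) || anyNA(event)) stop("missing survival times or events")
  if (any(time < 0)) stop("negative survival times")
  if (!any(event)) stop("log-rank test undefined: no events in either group")

  o <- order(time)
  tt <- time[o]; ee <- event[o]; aa <- in_a[o]
  n <- length(tt)
  # distinct observed times; risk set at time t is everyone with tt >= t
  r <- rle(tt)
  start <- cumsum(r$lengths) - r$lengths + 1L
  end <- cumsum(r$lengths)
  cs_e <- c(0, cumsum(ee))
  cs_ea <- c(0, cumsum(ee & aa))
  cs_a <- c(0, cumsum(aa))
  d <- cs_e[end + 1L] - cs_e[start]          # events at each distinct time
  da <- cs_ea[end + 1L] - cs_ea[start]
  nrisk <- n - start + 1L
  nrisk_a <- cs_a[n + 1L] - cs_a[start]
  keep <- d > 0L
  d <- d[keep]; da <- da[keep]
  nrisk <- nrisk[keep]; nrisk_a <- nrisk_a[keep]

  obs_a <- sum(da)
  exp_a <- sum(d * nrisk_a / nrisk)
  vok <- nrisk > 1L
  v <- sum((d * (nrisk_a / nrisk) * (1 - nrisk_a / nrisk) *
              (nrisk - d) / (nrisk - 1L))[vok])
  obs <- c(a = obs_a, b = sum(d) - obs_a)
  expd <- c(a = exp_a, b = sum(d) - exp_a)

  if (v <= 0) {
    chisq <- 0
    p <- 1
    direction <- NA_character_
  } else {
    chisq <- (obs_a - exp_a)^2 / v
    p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
    direction <- if (obs_a < exp_a) "a" else if (obs_a > exp_a) "b"
                 else NA_character_
  }
  structure(list(chisq = chisq, p_value = p, direction = direction,
                 observed = obs, expected = expd,
                 n = c(a = length(time_a), b = length(time_b))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group log-rank test\n")
  cat(sprintf("  chi-square = %.4g (1 df), p = %.4g\n", x$chisq, x$p_value))
  cat(sprintf("  observed/expected events: A %d/%.2f, B %d/%.2f\n",
              x$observed[1], x$expected[1], x$observed[2], x$expected[2]))
  if (!is.na(x$direction))
    cat(sprintf("  longer-survival group: %s\n", toupper(x$direction)))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Follow-up times (days).
#' @param event Logical event indicators (`FALSE` = censored).
#' @return A data frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (right-continuous survival
#'   probability just after `time`). The curve starts at 1 before the first
#'   observed time.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) > 0L)
  event <- as.logical(event)
  o <- order(time)
  tt <- time[o]; ee <- event[o]
  ut <- unique(tt)
  n <- length(tt)
  n_event <- vapply(ut, function(t) sum(ee[tt == t]), integer(1L))
  n_censor <- vapply(ut, function(t) sum(!ee[tt == t]), integer(1L))
  n_risk <- vapply(ut, function(t) sum(tt >= t), integer(1L))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both sides have at most 25 untied observations,
#' the tie-corrected normal approximation otherwise. Identical pooled values
#' give p = 1 by convention.
#'
#' @param x,y Numeric samples; missing values dropped.
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("wilcoxon_ranksum requires non-empty samples")
  pooled <- c(x, y)
  if (all(pooled == pooled[1L])) return(1)
  exact <- length(x) <= 25L && length(y) <= 25L && !anyDuplicated(pooled)
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = TRUE))
  min(1, res$p.value)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than the observed table's.
#' A zero row or column margin carries no information and returns p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("fisher_exact_2x2 requires a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Spearman rank correlation (mid-ranks)
#'
#' @param x,y Equal-length numeric vectors; pairs with missing values are
#'   removed, and at least 3 complete pairs are required. A constant vector
#'   leaves the correlation undefined; 0 is returned with a warning.
#' @return Spearman correlation coefficient.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("spearman_cor requires >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant vector: Spearman correlation undefined, returning 0")
    return(0)
  }
  stats::cor(x, y, method = "spearman")
}

#' Two-sided two-sample t-test p-value
#'
#' Welch by default (the group sizes in this pipeline are unequal); set
#' `equal_var = TRUE` for the pooled-variance variant. Degenerate inputs with
#' zero variance on both sides return 1 when the means agree and 0 otherwise,
#' with a warning.
#'
#' @param x,y Numeric samples, each with at least 2 non-missing values.
#' @param equal_var Assume equal variances (pooled t-test)?
#' @return Two-sided p-value.
#' @export
two_sample_t <- function(x, y, equal_var = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("two_sample_t requires >= 2 non-missing values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning("zero variance in both groups: degenerate t-test")
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = equal_var)$p.value
}
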