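# Shared fixtures, built in code. The default-scale cohort and its fit are
# computed once and cached because several files inspect them.

.cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cache$cohort))
    .cache$cohort <- generate_cohort(sim_config(seed = 1))
  .cache$cohort
}

default_run <- function() {
  if (is.null(.cache$run))
    .cache$run <- suppressWarnings(run_pipeline(cohort = default_cohort()))
  .cache$run
}

# a tiny hand-made clinical table: 6 samples covering the eligibility paths
tiny_clinical <- function() {
  samples <- data.frame(
    sample_id = sprintf("P%d", 1:6),
    age = c(55, 60, 48, 72, 63, 50),
    stage = c("III", "III", "IV", "III", "II", "III"),
    batch = "B1",
    event_observed = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    event_day = c(396, 400, NA, 250, 300, 520),
    last_followup_day = c(NA, NA, 618, NA, NA, NA),
    stringsAsFactors = FALSE)
  treatments <- rbind(
    data.frame(sample_id = "P1", drug = c("paclitaxel", "carboplatin"),
               start_day = 10, cycles = 6),
    data.frame(sample_id = "P2", drug = c("paclitaxel", "carboplatin", "gemcitabine"),
               start_day = c(10, 10, 200), cycles = c(6, 6, 2)),
    data.frame(sample_id = "P3", drug = c("paclitaxel", "carboplatin"),
               start_day = c(5, 45), cycles = 6),
    data.frame(sample_id = "P4", drug = c("paclitaxel", "carboplatin"),
               start_day = 12, cycles = c(6, 3)),
    data.frame(sample_id = "P5", drug = c("paclitaxel", "carboplatin"),
               start_day = 8, cycles = 6),
    data.frame(sample_id = "P6", drug = "paclitaxel",
               start_day = 9, cycles = 6))
  clinical_table(samples, treatments)
}

# survival data frame shorthand
pfs_df <- function(ids, time, event) {
  data.frame(sample_id = ids, time = time, event = as.logical(event),
             stringsAsFactors = FALSE)
}

# exhaustive two-sided Wilcoxon rank-sum p-value by enumerating all splits
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  splits <- utils::combn(length(pooled), nx)
  stats <- apply(splits, 2L, function(ix) sum(r[ix]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# two-sided Fisher exact p by direct hypergeometric enumeration
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# naive complete-linkage oracle: recompute every cluster-pair distance as the
# max over member pairs of the original matrix, same lexicographic tie-break
complete_linkage_oracle <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(clusters) > 2L) {
    step <- oracle_merge_once(d, clusters)
    clusters <- step$clusters
    heights <- c(heights, step$height)
  }
  list(cut2 = lapply(clusters, sort), heights = heights)
}

oracle_merge_once <- function(d, clusters) {
  k <- length(clusters)
  best <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    h <- max(d[clusters[[i]], clusters[[j]]])
    key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
    if (is.null(best) || h < best$h - 1e-12 ||
        (abs(h - best$h) <= 1e-12 &&
         (key[1] < best$key[1] ||
          (key[1] == best$key[1] && key[2] < best$key[2])))) {
      best <- list(h = h, i = i, j = j, key = key)
    }
  }
  merged <- c(clusters[[best$i]], clusters[[best$j]])
  clusters <- clusters[-c(best$i, best$j)]
  clusters[[length(clusters) + 1L]] <- merged
  list(clusters = clusters, height = best$h)
}
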