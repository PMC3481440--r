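# F-score discretization, Jaccard distances, complete-linkage clustering and
# classification integration.

mk_test_rec <- function(feature, contrast, p, direction, g1, g2,
                        modality = "copy_number") {
  list(feature_id = feature, modality = modality, contrast = contrast,
       p_value = p, direction = direction, group1 = g1, group2 = g2,
       flags = character())
}

test_that("F-scores encode status through the survival direction", {
  ids <- c("k1", "k2", "k3", "k4")
  status <- matrix(c("gain", "normal", "loss", NA), 1,
                   dimnames = list("g1", ids))
  # gain tested vs normal; the normal group survives longer
  tests <- structure(list(mk_test_rec("g1", "gain_vs_normal", 0.01, "group2",
                                      "k1", "k2")), class = "feature_tests")
  f <- assign_fscores(tests, status)
  expect_equal(unname(f$scores[1, ]), c(-1L, 1L, 0L, 0L))

  # loss contrast: gains and missing are the unknown status
  status2 <- matrix(c("loss", "normal", "gain", NA), 1,
                    dimnames = list("g1", ids))
  tests2 <- structure(list(mk_test_rec("g1", "loss_vs_normal", 0.01, "group1",
                                       "k1", "k2")), class = "feature_tests")
  f2 <- assign_fscores(tests2, status2)
  expect_equal(unname(f2$scores[1, ]), c(1L, -1L, 0L, 0L))

  # methylation: every non-missing sample is in one of the two groups
  status3 <- matrix(c("hyper", "mid", "hypo", NA), 1,
                    dimnames = list("cg1", ids))
  tests3 <- structure(list(mk_test_rec("cg1", "hyper_vs_rest", 0.01, "group2",
                                       "k1", c("k2", "k3"), "methylation")),
                      class = "feature_tests")
  f3 <- assign_fscores(tests3, status3)
  expect_equal(unname(f3$scores[1, ]), c(-1L, 1L, 1L, 0L))
})

test_that("a feature selected under both contrasts is scored by the smaller p", {
  ids <- c("k1", "k2", "k3")
  status <- matrix(c("gain", "normal", "loss"), 1, dimnames = list("g1", ids))
  tests <- structure(list(
    mk_test_rec("g1", "gain_vs_normal", 0.01, "group2", "k1", "k2"),
    mk_test_rec("g1", "loss_vs_normal", 0.03, "group2", "k3", "k2")),
    class = "feature_tests")
  f <- assign_fscores(tests, status)
  expect_equal(nrow(f$scores), 1L)
  expect_equal(f$provenance$contrast, "gain_vs_normal")
  expect_equal(unname(f$scores[1, ]), c(-1L, 1L, 0L))  # loss scored 0
})

test_that("F-scores are invariant to which group the log-rank saw first", {
  # swapping the argument order flips direction labels but the winning
  # group's identity, hence the scores, must not change
  t1 <- logrank_test(c(1, 2, 3), c(TRUE, TRUE, TRUE),
                     c(9, 10, 11), c(TRUE, TRUE, TRUE))
  t2 <- logrank_test(c(9, 10, 11), c(TRUE, TRUE, TRUE),
                     c(1, 2, 3), c(TRUE, TRUE, TRUE))
  longer1 <- if (t1$direction == "a") "first_arg" else "second_arg"
  longer2 <- if (t2$direction == "a") "second_arg" else "first_arg"
  expect_equal(longer1, longer2)
})

test_that("Jaccard distance matches the hand examples", {
  s <- cbind(k1 = c(1L, 0L, -1L), k2 = c(1L, 1L, -1L))
  rownames(s) <- sprintf("f%d", 1:3)
  d <- jaccard_distance(s)
  expect_equal(d["k1", "k2"], 1 / 3)
  expect_equal(diag(d), c(k1 = 0, k2 = 0))

  s2 <- cbind(k1 = c(1L, 1L, 0L), k2 = c(-1L, -1L, 0L))
  expect_equal(jaccard_distance(s2)["k1", "k2"], 1)

  s3 <- cbind(k1 = c(1L, 0L, -1L), k2 = c(1L, 0L, -1L))
  expect_equal(jaccard_distance(s3)["k1", "k2"], 0)

  # mutually uninformative pair: defined as 1 and flagged
  s4 <- cbind(k1 = c(0L, 0L), k2 = c(0L, 0L), k3 = c(1L, 0L))
  expect_warning(d4 <- jaccard_distance(s4), "no informative")
  expect_equal(d4["k1", "k2"], 1)
  expect_equal(attr(d4, "uninformative_pairs"), 1L)
})

test_that("complete linkage matches the brute-force oracle on small inputs", {
  set.seed(51)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    # ternary profiles give heavily tied Jaccard distances
    s <- matrix(sample(c(-1L, 0L, 1L), n * 6, replace = TRUE), 6, n,
                dimnames = list(sprintf("f%d", 1:6), sprintf("k%d", 1:n)))
    if (any(colSums(s != 0L) == 0)) next
    d <- suppressWarnings(jaccard_distance(s))
    mine <- chemoclust:::complete_linkage(d)
    oracle <- complete_linkage_oracle(d)
    expect_equal(mine$heights[seq_len(n - 2)], oracle$heights)
    expect_setequal(lapply(mine$cut2, sort), oracle$cut2)
  }
})

test_that("complete linkage heights agree with hclust on tie-free distances", {
  set.seed(52)
  x <- matrix(stats::rnorm(10 * 4), 10, 4)
  d <- as.matrix(stats::dist(t(x)))
  dimnames(d) <- list(sprintf("k%d", 1:4), sprintf("k%d", 1:4))
  mine <- chemoclust:::complete_linkage(d)
  ref <- stats::hclust(stats::as.dist(d), method = "complete")
  expect_equal(mine$heights, ref$height, tolerance = 1e-12)
})

test_that("clustering separates blocks and labels the unfavorable one PPT", {
  ids <- sprintf("k%d", 1:10)
  s <- cbind(matrix(rep(c(-1L, -1L, 0L), 4), 3), matrix(rep(c(1L, 1L, 0L), 6), 3))
  dimnames(s) <- list(sprintf("f%d", 1:3), ids)
  f <- structure(list(scores = s, provenance = NULL), class = "fscore_matrix")
  pfs <- pfs_df(ids, c(50, 60, 70, 80, 500, 520, 540, 560, 580, 600),
                rep(TRUE, 10))
  cl <- cluster_samples(f, pfs)
  expect_setequal(cl$ppt_ids, ids[1:4])
  expect_setequal(cl$gpt_ids, ids[5:10])
  expect_lt(cl$logrank_p, 0.05)
  expect_true(cl$proposed)

  # permuting sample order permutes but does not change membership
  perm <- c(7, 2, 9, 4, 1, 10, 3, 6, 5, 8)
  f2 <- structure(list(scores = s[, perm], provenance = NULL),
                  class = "fscore_matrix")
  cl2 <- cluster_samples(f2, pfs[perm, ])
  expect_setequal(cl2$ppt_ids, cl$ppt_ids)
})

test_that("degenerate score matrices yield a flagged all-GPT result", {
  ids <- sprintf("k%d", 1:5)
  f <- structure(list(scores = matrix(integer(), 0, 5,
                                      dimnames = list(NULL, ids)),
                      provenance = NULL), class = "fscore_matrix")
  cl <- cluster_samples(f, pfs_df(ids, 1:5, rep(TRUE, 5)))
  expect_equal(cl$gpt_ids, ids)
  expect_false(cl$proposed)
  expect_true("degenerate" %in% cl$flags)
})

test_that("integration takes the union of PPT sets against the complement", {
  ids <- sprintf("k%d", 1:20)
  mk_cl <- function(ppt) {
    structure(list(assignment = stats::setNames(ifelse(ids %in% ppt, 1L, 2L), ids),
                   ppt_ids = ppt, gpt_ids = setdiff(ids, ppt),
                   logrank_p = 0.01, proposed = TRUE, flags = character()),
              class = "cluster_result")
  }
  pfs <- pfs_df(ids, seq(100, 2000, length.out = 20), rep(TRUE, 20))
  out <- integrate_classifications(mk_cl(ids[1:5]), mk_cl(ids[4:9]), pfs)
  expect_setequal(out$ppt_ids, ids[1:9])
  expect_setequal(out$overlap_ids, ids[4:5])
  expect_equal(length(out$ppt_ids) + length(out$gpt_ids), 20L)

  # both empty: everything GPT, nothing proposed
  out0 <- integrate_classifications(mk_cl(character()), mk_cl(character()), pfs)
  expect_length(out0$ppt_ids, 0L)
  expect_false(out0$proposed)
})
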