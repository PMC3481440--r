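# Location/scale batch correction: identity cases, the hand-evaluated
# two-batch example, median alignment and idempotence.

mk_expr <- function(v, ids = NULL) {
  if (is.null(dim(v))) v <- matrix(v, 1, dimnames = list("g1", ids))
  omics_matrix(v, "expression")
}

test_that("single batch is the identity map for both modalities", {
  set.seed(11)
  v <- matrix(stats::rnorm(40, 7), 4, 10,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:10)))
  out <- suppressWarnings(correct_expression(mk_expr(v), rep("b1", 10)))
  expect_equal(out$matrix$values, v, tolerance = 1e-12)

  b <- matrix(stats::runif(40), 4, 10, dimnames = dimnames(v))
  outm <- suppressWarnings(correct_methylation(omics_matrix(b, "methylation"),
                                               rep("b1", 10)))
  expect_equal(outm$matrix$values, b, tolerance = 1e-12)
})

test_that("two-batch expression example matches direct evaluation of the L/S formula", {
  v <- c(1, 2, 3, 11, 12, 13)
  ids <- sprintf("s%d", 1:6)
  batches <- rep(c("A", "B"), each = 3)
  out <- suppressWarnings(correct_expression(mk_expr(v, ids),
                                             stats::setNames(batches, ids)))
  g <- out$matrix$values[1, ]
  # direct arithmetic: M_i, sigma_i from the pooled six values
  m_i <- stats::median(v); s_i <- stats::sd(v)
  expect_adj <- c(m_i + (c(1, 2, 3) - 2) * s_i / 1,
                  m_i + (c(11, 12, 13) - 12) * s_i / 1)
  expect_equal(unname(g), expect_adj, tolerance = 1e-12)
  # adjusted per-batch medians equal the pooled median
  expect_equal(stats::median(g[1:3]), m_i, tolerance = 1e-12)
  expect_equal(stats::median(g[4:6]), m_i, tolerance = 1e-12)
  # and per-batch scales equal the pooled scale
  expect_equal(stats::sd(g[1:3]), s_i, tolerance = 1e-9)
})

test_that("degenerate batches collapse to the pooled median and are flagged", {
  v <- c(5, 5, 5, 1, 2, 9)   # batch A constant
  ids <- sprintf("s%d", 1:6)
  out <- suppressWarnings(correct_expression(mk_expr(v, ids),
                                             rep(c("A", "B"), each = 3)))
  m_i <- stats::median(v)
  expect_equal(unname(out$matrix$values[1, 1:3]), rep(m_i, 3))
  tab <- out$report$table
  expect_equal(tab$flag[tab$batch == "A"], "zero_scale")
})

test_that("MAD and SD estimators agree in distribution on normal data", {
  set.seed(12)
  v <- matrix(stats::rnorm(100 * 3, 5, 2), 100, 3 * 1)
  v <- cbind(v, matrix(stats::rnorm(300, 8, 1), 100, 3))
  dimnames(v) <- list(sprintf("g%d", 1:100), sprintf("s%d", 1:6))
  bat <- rep(c("A", "B"), each = 3)
  sd_out <- suppressWarnings(correct_expression(mk_expr(v), bat, "sd"))
  mad_out <- suppressWarnings(correct_expression(mk_expr(v), bat, "mad"))
  # both estimators align every per-batch median onto the pooled median
  gm <- chemoclust:::row_medians(v)
  for (b in c("A", "B")) {
    expect_equal(chemoclust:::row_medians(sd_out$matrix$values[, bat == b]),
                 gm, tolerance = 1e-9)
    expect_equal(chemoclust:::row_medians(mad_out$matrix$values[, bat == b]),
                 gm, tolerance = 1e-9)
  }
})

test_that("beta rescaling matches the piecewise map and stays monotone in [0,1]", {
  # M_i = 0.5, M_ij = 0.4 hand values
  expect_equal(chemoclust:::beta_map(c(0.2, 0.7, 0, 1, 0.4), 0.5, 0.4),
               c(0.25, 0.75, 0, 1, 0.5))
  set.seed(13)
  for (i in 1:10) {
    b <- sort(stats::runif(15))
    out <- chemoclust:::beta_map(b, stats::runif(1, 0.2, 0.8),
                                 stats::runif(1, 0.2, 0.8))
    expect_true(all(diff(out) >= -1e-12))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("correction aligns per-batch medians to the global median (odd batches)", {
  set.seed(14)
  n_per <- 9  # odd within-batch count: the batch median is an order statistic
  v <- matrix(stats::rnorm(60 * 4 * n_per, 6, 1.5), 60, 4 * n_per)
  dimnames(v) <- list(sprintf("g%d", 1:60), sprintf("s%d", seq_len(4 * n_per)))
  bat <- rep(sprintf("b%d", 1:4), each = n_per)
  gm <- chemoclust:::row_medians(v)

  oute <- suppressWarnings(correct_expression(mk_expr(v), bat))
  for (b in unique(bat))
    expect_equal(chemoclust:::row_medians(oute$matrix$values[, bat == b]),
                 gm, tolerance = 1e-9)

  bv <- matrix(stats::runif(60 * 4 * n_per), 60, 4 * n_per, dimnames = dimnames(v))
  gmb <- chemoclust:::row_medians(bv)
  outb <- suppressWarnings(correct_methylation(omics_matrix(bv, "methylation"), bat))
  for (b in unique(bat))
    expect_equal(chemoclust:::row_medians(outb$matrix$values[, bat == b]),
                 gmb, tolerance = 1e-9)
})

test_that("expression correction is idempotent within estimator noise", {
  set.seed(15)
  v <- matrix(stats::rnorm(50 * 40, 7, 1.2), 50, 40,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:40)))
  bat <- rep(c("A", "B"), each = 20)
  once <- suppressWarnings(correct_expression(mk_expr(v), bat))
  twice <- suppressWarnings(correct_expression(once$matrix, bat))
  expect_lt(max(abs(twice$matrix$values - once$matrix$values)), 0.12)
})

test_that("copy-number matrices are refused by batch correction", {
  v <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(correct_expression(omics_matrix(v, "copy_number"), c("A", "A")),
               "not batch-corrected")
})

test_that("missing values are excluded from statistics and stay missing", {
  set.seed(16)
  v <- matrix(stats::rnorm(6 * 10, 5), 6, 10,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
  v[1, 3] <- NA; v[4, 8] <- NA
  out <- suppressWarnings(correct_expression(mk_expr(v), rep(c("A", "B"), each = 5)))
  expect_true(is.na(out$matrix$values[1, 3]))
  expect_true(is.na(out$matrix$values[4, 8]))
  expect_false(anyNA(out$matrix$values[2, ]))
})
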