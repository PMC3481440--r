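# Status categorization, the log-rank scan gate, and the two refinement
# funnels.

test_that("copy-number categorization uses the printed inclusive boundaries", {
  v <- matrix(c(0.4, 0.41, -0.5, -0.51, 0, NA), 1,
              dimnames = list("g1", sprintf("s%d", 1:6)))
  st <- categorize_cn(omics_matrix(v, "copy_number"))
  expect_equal(unname(st[1, ]),
               c("normal", "gain", "normal", "loss", "normal", NA))
})

test_that("methylation categorization uses per-feature interpolated quantiles", {
  v <- matrix((1:100) / 100, 1, dimnames = list("cg1", sprintf("s%d", 1:100)))
  cat <- categorize_meth(omics_matrix(v, "methylation"))
  lo <- stats::quantile((1:100) / 100, 0.25)  # 25.75/100 under interpolation
  expect_equal(unname(cat$cutoffs$lo), unname(lo))
  expect_equal(sum(cat$status == "hypo"), sum((1:100) / 100 < lo))
  expect_equal(sum(cat$status == "hyper"), sum((1:100) / 100 > stats::quantile((1:100) / 100, 0.75)))

  # constant feature: everything mid
  vc <- matrix(0.5, 1, 10, dimnames = list("cg1", sprintf("s%d", 1:10)))
  expect_true(all(categorize_meth(omics_matrix(vc, "methylation"))$status == "mid"))

  # missing values excluded from the quantile computation
  vna <- matrix(c(NA, (1:9) / 10), 1, dimnames = list("cg1", sprintf("s%d", 1:10)))
  catna <- categorize_meth(omics_matrix(vna, "methylation"))
  expect_equal(unname(catna$cutoffs$lo), unname(stats::quantile((1:9) / 10, 0.25)))
  expect_true(is.na(catna$status[1, 1]))
})

test_that("the minimum group size rule reads 15 percent or 13, whichever is larger", {
  expect_equal(min_group_size(85), 13L)
  expect_equal(min_group_size(50), 13L)   # floor of 13 binds for small cohorts
  expect_equal(min_group_size(200), 30L)  # ceil(0.15 n) binds for large ones
})

test_that("the scan gates group sizes and keeps sub-alpha contrasts with direction", {
  set.seed(31)
  n <- 85
  ids <- sprintf("s%02d", 1:n)
  # feature A: 20 gain carriers with hazard x4; feature B: 5 gains only
  carrier <- c(rep(TRUE, 20), rep(FALSE, n - 20))
  time <- round(stats::rexp(n, ifelse(carrier, 4, 1) / 300)) + 1
  pfs <- pfs_df(ids, time, rep(TRUE, n))
  status <- rbind(
    A = ifelse(carrier, "gain", "normal"),
    B = c(rep("gain", 5), rep("normal", n - 5)))
  colnames(status) <- ids
  tests <- scan_features(status, pfs, "copy_number")
  df <- as.data.frame(tests)
  expect_true("A" %in% df$feature_id)
  expect_false("B" %in% df$feature_id)  # 5 < 13: never tested
  # gain carriers die faster, so the normal group is the longer-survival one
  expect_equal(df$direction[df$feature_id == "A"], "group2")
  expect_setequal(tests[[1]]$group1, ids[carrier])
})

test_that("a planted hazard effect is selected in most seeded replicates", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 85
    ids <- sprintf("s%02d", 1:n)
    carrier <- c(rep(TRUE, 18), rep(FALSE, n - 18))
    time <- round(stats::rexp(n, ifelse(carrier, 4, 1) / 300)) + 1
    status <- matrix(ifelse(carrier, "gain", "normal"), 1,
                     dimnames = list("g", ids))
    length(scan_features(status, pfs_df(ids, time, rep(TRUE, n)),
                         "copy_number")) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("confounder refinement drops age- and stage-linked features", {
  set.seed(32)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  age <- seq(35, 85, length.out = n)
  samples <- data.frame(sample_id = ids, age = age,
                        stage = rep(c("III", "IV"), n / 2),  # age-balanced
                        batch = "B1", event_observed = TRUE,
                        event_day = 100, last_followup_day = NA,
                        stringsAsFactors = FALSE)
  cl <- clinical_table(samples)
  mk_test <- function(g1, g2, modality = "copy_number", feature = "f") {
    structure(list(list(feature_id = feature, modality = modality,
                        contrast = if (modality == "copy_number")
                          "gain_vs_normal" else "hypo_vs_rest",
                        p_value = 0.01, direction = "group2",
                        group1 = g1, group2 = g2, flags = character())),
              class = "feature_tests")
  }
  # age-separated groups are dropped, age-balanced groups kept
  old <- ids[age > 70]; young <- ids[age <= 70]
  out <- refine_confounders(mk_test(old, young), cl)
  expect_length(out, 0L)
  expect_equal(attr(out, "dropped")[[1]]$flags, "age_confounded")
  balanced <- ids[rep(c(TRUE, TRUE, FALSE, FALSE), n / 4)]  # age/stage balanced
  out2 <- refine_confounders(mk_test(balanced, setdiff(ids, balanced)), cl)
  expect_length(out2, 1L)

  # stage-aligned groups are dropped by the Fisher filter
  stage3 <- ids[samples$stage == "III"]
  out3 <- refine_confounders(mk_test(stage3, setdiff(ids, stage3)), cl)
  expect_length(out3, 0L)
  expect_true("stage_confounded" %in% attr(out3, "dropped")[[1]]$flags)

  # all samples in one stage: the stage filter is vacuous (zero margin)
  samples1 <- samples; samples1$stage <- "III"
  out4 <- refine_confounders(mk_test(old, young), clinical_table(samples1))
  expect_false(any(vapply(attr(out4, "dropped"),
                          function(t) "stage_confounded" %in% t$flags,
                          logical(1))))

  # methylation: a beta profile tracking age is dropped via Spearman
  beta <- matrix(age / 100 + stats::rnorm(n, 0, 0.02), 1,
                 dimnames = list("cg1", ids))
  bm <- omics_matrix(pmin(pmax(beta, 0), 1), "methylation")
  tm <- mk_test(ids[1:20], ids[21:n], "methylation", "cg1")
  outm <- refine_confounders(tm, cl, beta = bm)
  expect_length(outm, 0L)
  expect_true("age_confounded" %in% attr(outm, "dropped")[[1]]$flags)
})

test_that("fold-change refinement keeps concordant features, boundary inclusive", {
  ids <- sprintf("s%d", 1:8)
  g1 <- ids[1:4]; g2 <- ids[5:8]
  mk_test <- function(feature) {
    structure(list(list(feature_id = feature, modality = "copy_number",
                        contrast = "gain_vs_normal", p_value = 0.01,
                        direction = "group1", group1 = g1, group2 = g2,
                        flags = character())), class = "feature_tests")
  }
  expr <- matrix(0, 3, 8, dimnames = list(c("flat", "exact", "big"), ids))
  expr["exact", g1] <- log2(1.3)   # fold change exactly 1.3
  expr["big", g1] <- 1
  em <- omics_matrix(expr, "expression")
  expect_length(refine_foldchange(mk_test("flat"), em), 0L)
  expect_length(refine_foldchange(mk_test("exact"), em), 1L)
  expect_length(refine_foldchange(mk_test("big"), em), 1L)
  # unmapped methylation feature is dropped and flagged
  tm <- mk_test("cg9")
  tm[[1]]$modality <- "methylation"
  out <- refine_foldchange(tm, em, feature_gene_map = c(cg9 = "absent_gene"))
  expect_length(out, 0L)
  expect_equal(attr(out, "dropped")[[1]]$flags, "no_expression")
})

test_that("the funnel never grows along refinement", {
  run <- default_run()
  for (mod in c("cn", "meth")) {
    f <- run$fit[[mod]]$funnel
    expect_gte(f[["scanned"]], f[["after_confounders"]])
    expect_gte(f[["after_confounders"]], f[["after_foldchange"]])
  }
})

test_that("a null cohort's scan retains about an alpha-level fraction", {
  # no planted effects: hypo/hyper contrasts are tested for every CpG, and the
  # fraction of tests below alpha estimates the scan's type-I level (counted
  # per contrast test; the per-feature union of the two contrasts is ~2 alpha
  # by construction)
  rates <- vapply(1:8, function(s) {
    co <- generate_cohort(null_config(n_samples = 200, n_genes = 100,
                                      n_cpg = 600, n_batches = 4, seed = 300 + s))
    out <- suppressWarnings(assign_cohorts(co$clinical))
    pfs <- derive_pfs(co$clinical)
    train <- out$training
    st <- categorize_meth(chemoclust:::subset_samples(co$methylation, train))$status
    tests <- scan_features(st, pfs[match(train, pfs$sample_id), ], "methylation",
                           keep_all = TRUE)
    df <- as.data.frame(tests)
    mean(df$p_value < 0.05)
  }, numeric(1))
  expect_gte(mean(rates), 0.02)
  expect_lte(mean(rates), 0.09)
})
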