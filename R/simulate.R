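# Synthetic multi-omics cohort generator.
#
# Emulates the statistical structure the analysis assumes: per-batch
# location/scale shifts on log2 expression and median shifts on beta values;
# a contiguous copy-number-amplified gene segment with concordant expression
# up-regulation and shorter PFS in one planted subtype; a hypomethylated CpG
# set (with concordant expression change in the mapped genes) and shorter
# PFS in a second subtype; age/stage-confounded decoy features; treatment
# histories that satisfy the training rules, only the testing rules, or fail
# selection; and right-censored survival. Ground-truth labels and planted
# feature lists ride along so every downstream stage is testable.

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the generator's study conditions: a cohort of 200 samples in
#' 13 batches (about 85 training / 83 testing after selection), 2,000 genes
#' and 1,000 CpG sites, a 40-gene amplified segment on chromosome 1 (gain
#' mean 0.8 log2 ratio, expression shift log2(1.5)), 40 hypomethylated CpGs
#' (beta shift -0.3) mapped to expression-shifted genes, hazard ratio 3 for
#' either poor-prognosis subtype against a 396-day baseline median PFS, and
#' about 17% censoring.
#'
#' @param n_samples,n_genes,n_cpg,n_batches Cohort dimensions.
#' @param batch_location_sd SD (log2 units) of per-batch additive shifts on
#'   expression.
#' @param batch_scale_range Multiplicative interval for per-batch expression
#'   scale factors.
#' @param beta_batch_median_shift Half-width (beta units) of per-batch
#'   additive median shifts on beta values.
#' @param frac_cn_ppt,frac_meth_ppt Fractions of samples in the planted
#'   copy-number and methylation poor-prognosis subtypes (the remainder are
#'   good-prognosis; the three subtypes partition the cohort).
#' @param planted_segment List with `chromosome`, `start` (gene index) and
#'   `length` of the contiguous amplified segment; must fit inside
#'   `n_genes`.
#' @param cn_gain_mean Mean log2 ratio of the amplified segment in cn-PPT
#'   samples (above the 0.4 gain threshold in expectation).
#' @param expr_shift Concordant log2 expression shift on planted genes.
#' @param beta_hypo_shift Beta reduction on planted CpGs in meth-PPT samples
#'   (values clipped back into \[0, 1\]).
#' @param n_planted_cpg Number of planted hypomethylated CpG sites.
#' @param cn_noise_sd,expr_noise_sd,beta_noise_sd Measurement noise SDs.
#' @param baseline_median_pfs Median PFS (days) of good-prognosis samples.
#' @param ppt_hazard_ratio Hazard multiplier for either planted subtype.
#' @param survival_shape Weibull shape of the survival law (1 =
#'   exponential).
#' @param censoring_rate Target fraction of censored samples, realised via
#'   independent uniform administrative censoring over a window calibrated
#'   to the baseline hazard (0 disables censoring).
#' @param age_range Uniform age range (years).
#' @param age_log_hazard Log-hazard increase per year of age over 60 (mild
#'   by default, so age-confounded decoys can reach the survival scan).
#' @param stage4_frac Fraction of stage-IV samples (the rest are stage III,
#'   apart from selection-failing samples re-labelled to other stages).
#' @param frac_training,frac_testing Fractions of samples given treatment
#'   histories satisfying the training rules, or only the testing rules;
#'   the remainder fail selection. Assigned stratified by subtype.
#' @param n_decoy_confounded Number of decoy features (half copy-number
#'   features whose gains concentrate in old samples, half CpGs tracking
#'   age) for the confounder refinement to remove.
#' @param missing_rate Fraction of missing entries in the expression and
#'   copy-number matrices.
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   cohort.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 200L, n_genes = 2000L, n_cpg = 1000L,
                       n_batches = 13L,
                       batch_location_sd = 0.3,
                       batch_scale_range = c(0.8, 1.25),
                       beta_batch_median_shift = 0.04,
                       frac_cn_ppt = 0.21, frac_meth_ppt = 0.26,
                       planted_segment = NULL,
                       cn_gain_mean = 0.8, expr_shift = log2(1.8),
                       beta_hypo_shift = 0.3, n_planted_cpg = NULL,
                       cn_noise_sd = 0.2, expr_noise_sd = 0.35,
                       beta_noise_sd = 0.08,
                       baseline_median_pfs = 396,
                       ppt_hazard_ratio = 3, survival_shape = 1,
                       censoring_rate = 0.17,
                       age_range = c(34, 87), age_log_hazard = 0,
                       stage4_frac = 0.17,
                       frac_training = 0.425, frac_testing = 0.415,
                       n_decoy_confounded = NULL,
                       missing_rate = 0.02, seed = 1L) {
  # planted structure scales with the panel when not given explicitly:
  # a 40-gene segment at index 101 and 40 CpGs at full size (2,000 genes /
  # 1,000 CpGs), proportionally smaller for reduced panels
  if (is.null(planted_segment)) {
    len <- max(2L, min(40L, n_genes %/% 8L))
    planted_segment <- list(chromosome = "1",
                            start = min(101L, max(1L, n_genes - len + 1L)),
                            length = len)
  }
  if (is.null(n_planted_cpg)) n_planted_cpg <- max(2L, min(40L, n_cpg %/% 8L))
  if (is.null(n_decoy_confounded))
    n_decoy_confounded <- min(20L, n_cpg %/% 10L + n_genes %/% 20L)
  fracs <- c(frac_cn_ppt, frac_meth_ppt, censoring_rate, stage4_frac,
             frac_training, frac_testing, missing_rate)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (frac_cn_ppt + frac_meth_ppt > 1)
    stop("subtype fractions must sum to at most 1")
  if (frac_training + frac_testing > 1)
    stop("cohort fractions must sum to at most 1")
  if (ppt_hazard_ratio <= 0) stop("ppt_hazard_ratio must be positive")
  if (survival_shape <= 0) stop("survival_shape must be positive")
  seg_end <- planted_segment$start + planted_segment$length - 1L
  if (planted_segment$start < 1L || seg_end > n_genes)
    stop("planted segment must fit inside n_genes")
  if (n_planted_cpg > n_cpg) stop("n_planted_cpg exceeds n_cpg")
  if (planted_segment$length + n_planted_cpg + n_decoy_confounded %/% 2L > n_genes)
    stop("planted genes, CpG-mapped genes and decoys exceed n_genes")
  for (fr in c(frac_cn_ppt, frac_meth_ppt)) {
    if (fr > 0 && round(fr * n_samples) < 2L)
      stop("a planted subgroup would have fewer than 2 samples")
  }
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

#' Null-effect variant of a simulation configuration
#'
#' Convenience wrapper zeroing every planted effect (hazard ratio 1, no
#' copy-number gain, no methylation or expression shift, no decoys, no
#' age-hazard link) so that all marginal feature distributions are
#' exchangeable across the truth subtypes.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(...) {
  args <- list(ppt_hazard_ratio = 1, cn_gain_mean = 0, beta_hypo_shift = 0,
               expr_shift = 0, n_decoy_confounded = 0L, age_log_hazard = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# administrative censoring window such that, at the baseline exponential
# hazard, P(censored) equals the target rate: solve (1 - e^-x)/x = rate for
# x = lambda * W.
censor_window <- function(rate, median_pfs) {
  if (rate <= 0) return(Inf)
  f <- function(x) (1 - exp(-x)) / x - rate
  x <- stats::uniroot(f, c(1e-8, 1e6))$root
  x * median_pfs / log(2)
}

#' Generate a synthetic multi-omics cohort
#'
#' @param config A [sim_config()].
#' @return An object of class `"synthetic_cohort"`: `expression`,
#'   `copy_number`, `methylation` (`omics_matrix`), `clinical`
#'   (`clinical_table`), `truth_labels` (named vector over `cn_ppt`,
#'   `meth_ppt`, `gpt` partitioning the samples), `truth_features` (planted
#'   gene ids, CpG ids, decoy ids), `intended_cohort` (the treatment-rule
#'   role each sample was built to satisfy) and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_samples)
  ids <- sprintf("S%04d", seq_len(n))

  # ---- truth subtypes (a partition) ----
  n_cn <- round(config$frac_cn_ppt * n)
  n_meth <- round(config$frac_meth_ppt * n)
  labels <- sample(rep(c("cn_ppt", "meth_ppt", "gpt"),
                       c(n_cn, n_meth, n - n_cn - n_meth)))
  names(labels) <- ids

  # ---- clinical covariates ----
  age <- round(stats::runif(n, config$age_range[1L], config$age_range[2L]))
  stage <- ifelse(stats::runif(n) < config$stage4_frac, "IV", "III")
  batch <- sprintf("B%02d", sample(rep_len(seq_len(config$n_batches), n)))

  # ---- gene panel and planted segment ----
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  chr <- as.character(rep(1:22, each = ceiling(config$n_genes / 22))[seq_len(config$n_genes)])
  seg <- seq(config$planted_segment$start,
             length.out = config$planted_segment$length)
  chr[seg] <- as.character(config$planted_segment$chromosome)
  gene_ann <- data.frame(feature_id = genes, gene_symbol = genes,
                         chromosome = chr,
                         position = seq_len(config$n_genes) * 100000,
                         stringsAsFactors = FALSE)

  cpgs <- sprintf("cg%05d", seq_len(config$n_cpg))
  planted_cpg <- sample(config$n_cpg, config$n_planted_cpg)
  # planted CpGs map to genes outside the CN segment that carry a concordant
  # expression shift in meth-PPT samples
  meth_genes <- sample(setdiff(seq_len(config$n_genes), seg),
                       config$n_planted_cpg)
  cpg_gene <- genes[sample(config$n_genes, config$n_cpg, replace = TRUE)]
  cpg_gene[planted_cpg] <- genes[meth_genes]
  unmapped <- setdiff(which(stats::runif(config$n_cpg) < 0.05), planted_cpg)
  cpg_gene[unmapped] <- NA_character_
  cpg_ann <- data.frame(feature_id = cpgs, cpg_id = cpgs,
                        gene_symbol = cpg_gene, stringsAsFactors = FALSE)

  is_cn_ppt <- labels == "cn_ppt"
  is_meth_ppt <- labels == "meth_ppt"

  # ---- expression (log2) ----
  mu <- stats::runif(config$n_genes, 4, 10)
  expr <- mu + matrix(stats::rnorm(config$n_genes * n, 0, config$expr_noise_sd),
                      config$n_genes, n)
  expr[seg, is_cn_ppt] <- expr[seg, is_cn_ppt] + config$expr_shift
  expr[meth_genes, is_meth_ppt] <- expr[meth_genes, is_meth_ppt] + config$expr_shift
  dimnames(expr) <- list(genes, ids)

  # ---- copy number (log2 ratios; gene-level) ----
  cn <- matrix(stats::rnorm(config$n_genes * n, 0, config$cn_noise_sd),
               config$n_genes, n, dimnames = list(genes, ids))
  cn[seg, is_cn_ppt] <- stats::rnorm(length(seg) * sum(is_cn_ppt),
                                     config$cn_gain_mean, config$cn_noise_sd)

  # ---- decoy features confounded with age/stage ----
  n_decoy_cn <- config$n_decoy_confounded %/% 2L
  n_decoy_cpg <- config$n_decoy_confounded - n_decoy_cn
  decoy_cn <- decoy_cpg <- character()
  if (n_decoy_cn > 0L) {
    rows <- sample(setdiff(seq_len(config$n_genes), c(seg, meth_genes)),
                   n_decoy_cn)
    old <- age >= stats::quantile(age, 0.75)
    cn[rows, old] <- stats::rnorm(n_decoy_cn * sum(old),
                                  max(config$cn_gain_mean, 0.8),
                                  config$cn_noise_sd)
    decoy_cn <- genes[rows]
  }

  # ---- methylation beta values ----
  base_beta <- stats::runif(config$n_cpg, 0.15, 0.85)
  base_beta[planted_cpg] <- stats::runif(config$n_planted_cpg, 0.45, 0.75)
  beta <- base_beta + matrix(stats::rnorm(config$n_cpg * n, 0, config$beta_noise_sd),
                             config$n_cpg, n)
  beta[planted_cpg, is_meth_ppt] <- beta[planted_cpg, is_meth_ppt] -
    config$beta_hypo_shift
  if (n_decoy_cpg > 0L) {
    rows <- sample(setdiff(seq_len(config$n_cpg), planted_cpg), n_decoy_cpg)
    age_scaled <- (age - min(age)) / max(1, diff(range(age)))
    beta[rows, ] <- rep(0.15 + 0.6 * age_scaled, each = n_decoy_cpg) +
      stats::rnorm(n_decoy_cpg * n, 0, 0.05)
    decoy_cpg <- cpgs[rows]
  }
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(cpgs, ids)

  # ---- survival: proportional-hazards Weibull (shape 1 = exponential) ----
  hazard_mult <- ifelse(labels == "gpt", 1, config$ppt_hazard_ratio) *
    exp(config$age_log_hazard * (age - 60))
  shape <- config$survival_shape
  scale <- config$baseline_median_pfs / log(2)^(1 / shape)
  t_event <- scale * (stats::rexp(n) / hazard_mult)^(1 / shape)
  window <- censor_window(config$censoring_rate, config$baseline_median_pfs)
  c_admin <- if (is.finite(window)) stats::runif(n, 0, window) else rep(Inf, n)
  event <- t_event <= c_admin
  time <- pmax(round(pmin(t_event, c_admin)), 2)

  # ---- batch effects ----
  ub <- sort(unique(batch))
  delta <- stats::setNames(stats::rnorm(length(ub), 0, config$batch_location_sd), ub)
  scale_j <- stats::setNames(stats::runif(length(ub), config$batch_scale_range[1L],
                                          config$batch_scale_range[2L]), ub)
  bshift <- stats::setNames(stats::runif(length(ub), -config$beta_batch_median_shift,
                                         config$beta_batch_median_shift), ub)
  for (b in ub) {
    cols <- batch == b
    expr[, cols] <- expr[, cols] * scale_j[[b]] + delta[[b]]
    beta[, cols] <- pmin(pmax(beta[, cols] + bshift[[b]], 0), 1)
  }

  # ---- missingness (expression and copy number) ----
  if (config$missing_rate > 0) {
    expr[stats::runif(length(expr)) < config$missing_rate] <- NA_real_
    cn[stats::runif(length(cn)) < config$missing_rate] <- NA_real_
  }

  # ---- treatment histories, stratified by subtype ----
  role <- character(n); names(role) <- ids
  for (sub in unique(labels)) {
    members <- sample(which(labels == sub))
    k_train <- round(config$frac_training * length(members))
    k_test <- round(config$frac_testing * length(members))
    role[members[seq_len(k_train)]] <- "training"
    role[members[k_train + seq_len(k_test)]] <- "testing"
    rest <- members[seq_along(members) > k_train + k_test]
    role[rest] <- "fail"
  }
  other_drugs <- c("gemcitabine", "doxorubicin", "etoposide")
  trt <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    if (role[i] == "fail") {
      mode <- sample(c("start_delay", "cycles", "missing_drug", "stage"), 1L)
      if (mode == "stage") {
        stage[i] <- "other"
        trt[[id]] <- data.frame(sample_id = id,
                                drug = c("paclitaxel", "carboplatin"),
                                start_day = rep(sample(30, 1L), 2L),
                                cycles = rep(sample(4:8, 1L), 2L),
                                stringsAsFactors = FALSE)
      } else if (mode == "missing_drug") {
        trt[[id]] <- data.frame(sample_id = id, drug = "paclitaxel",
                                start_day = sample(30, 1L),
                                cycles = sample(4:8, 1L),
                                stringsAsFactors = FALSE)
      } else {
        start <- if (mode == "start_delay") sample(31:90, 1L) else sample(30, 1L)
        cyc <- if (mode == "cycles") sample(3, 1L) else sample(4:8, 1L)
        trt[[id]] <- data.frame(sample_id = id,
                                drug = c("paclitaxel", "carboplatin"),
                                start_day = rep(start, 2L),
                                cycles = rep(cyc, 2L),
                                stringsAsFactors = FALSE)
      }
    } else {
      start <- sample(30, 1L)
      cyc <- sample(4:8, 1L)
      rec <- data.frame(sample_id = id, drug = c("paclitaxel", "carboplatin"),
                        start_day = rep(start, 2L), cycles = rep(cyc, 2L),
                        stringsAsFactors = FALSE)
      if (role[i] == "testing") {
        rec <- rbind(rec, data.frame(
          sample_id = id, drug = sample(other_drugs, 1L),
          start_day = max(1, floor(time[i] / 2)), cycles = sample(6, 1L),
          stringsAsFactors = FALSE))
      }
      trt[[id]] <- rec
    }
  }
  treatments <- do.call(rbind, trt)
  rownames(treatments) <- NULL

  clinical <- clinical_table(
    data.frame(sample_id = ids, age = age, stage = stage, batch = batch,
               event_observed = event,
               event_day = ifelse(event, time, NA_real_),
               last_followup_day = ifelse(event, NA_real_, time),
               stringsAsFactors = FALSE),
    treatments)

  structure(list(
    expression = omics_matrix(expr, "expression", gene_ann),
    copy_number = omics_matrix(cn, "copy_number", gene_ann),
    methylation = omics_matrix(beta, "methylation", cpg_ann),
    clinical = clinical,
    truth_labels = labels,
    truth_features = list(cn_genes = genes[seg], cpgs = cpgs[planted_cpg],
                          meth_genes = genes[meth_genes],
                          decoy_cn = decoy_cn, decoy_cpg = decoy_cpg),
    intended_cohort = role,
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$truth_labels)
  cat(sprintf("synthetic_cohort: %d samples (%s), %d genes, %d CpGs, %d batches\n",
              length(x$truth_labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$expression$values), nrow(x$methylation$values),
              x$config$n_batches))
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Emits `expression.tsv`, `copy_number.tsv`, `methylation.tsv` (matrices),
#' `features_*.tsv` (annotations), `clinical.tsv`, `treatments.tsv` and
#' `truth.tsv` (`sample_id`, `subtype`) into `dir`. Missing values are
#' written as `NA`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mod in c("expression", "copy_number", "methylation")) {
    m <- cohort[[mod]]
    write_tsv_matrix(m$values, file.path(dir, paste0(mod, ".tsv")))
    utils::write.table(m$annotations,
                       file.path(dir, paste0("features_", mod, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  utils::write.table(cohort$clinical$samples, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$clinical$treatments,
                     file.path(dir, "treatments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(data.frame(sample_id = names(cohort$truth_labels),
                                subtype = unname(cohort$truth_labels)),
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the TSV files.
#' @return A list with `expression`, `copy_number`, `methylation`,
#'   `clinical` and (when present) `truth_labels`.
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (mod in c("expression", "copy_number", "methylation")) {
    out[[mod]] <- read_omics_matrix(file.path(dir, paste0(mod, ".tsv")), mod,
                                    file.path(dir, paste0("features_", mod, ".tsv")),
                                    collapse_genes = FALSE)
  }
  out$clinical <- read_clinical(file.path(dir, "clinical.tsv"),
                                file.path(dir, "treatments.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    tr <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
    out$truth_labels <- stats::setNames(tr$subtype, tr$sample_id)
  }
  out
}
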