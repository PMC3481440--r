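# Data containers and TSV readers/writers.
#
# Matrices are features-as-rows, samples-as-columns TSV with a header row and
# "NA" as the missing-value token. Dates are integer day offsets from the day
# of surgical resection (day 0).

#' Construct and validate an omics matrix
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Missing values allowed.
#' @param modality One of `"expression"` (log2 values), `"copy_number"`
#'   (log2 ratios) or `"methylation"` (beta values in \[0, 1\]).
#' @param annotations Optional per-feature data frame with a `feature_id`
#'   column and any of `gene_symbol`, `chromosome`, `position`, `cpg_id`.
#' @return An object of class `"omics_matrix"`.
#' @export
omics_matrix <- function(values,
                         modality = c("expression", "copy_number", "methylation"),
                         annotations = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("values must have rownames (features) and colnames (samples)")
  if (anyDuplicated(fid))
    stop("duplicate feature ids: ", paste(unique(fid[duplicated(fid)])[1:min(3, sum(duplicated(fid)))], collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", unique(sid[duplicated(sid)])[1L])
  if (modality == "methylation") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("beta value out of [0,1]: feature '%s', sample '%s', value %g",
                   fid[bad[1L, 1L]], sid[bad[1L, 2L]],
                   values[bad[1L, , drop = FALSE]]))
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (!"feature_id" %in% names(annotations))
      stop("annotations must contain a feature_id column")
    if (!all(fid %in% annotations$feature_id))
      stop("annotations missing for some features")
    annotations <- annotations[match(fid, annotations$feature_id), , drop = FALSE]
    rownames(annotations) <- NULL
  }
  structure(list(values = values, modality = modality,
                 annotations = annotations),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples (%d missing values)\n",
              x$modality, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Read a feature-by-sample TSV matrix
#'
#' Expects a header row of sample ids, a first column of feature ids, and
#' `NA` for missing values. Copy-number matrices with a gene-symbol
#' annotation are collapsed to one row per gene by averaging (multiple
#' measurements mapping to the same gene are averaged at load time).
#'
#' @param path TSV file path.
#' @inheritParams omics_matrix
#' @param annotations_path Optional TSV with per-feature annotations
#'   (`feature_id`, `gene_symbol`, `chromosome`, `position`, ...).
#' @param collapse_genes Average rows sharing a gene symbol (default: only
#'   for copy-number matrices with annotations).
#' @return An `omics_matrix`.
#' @export
read_omics_matrix <- function(path, modality, annotations_path = NULL,
                              collapse_genes = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix TSV needs a feature-id column plus samples")
  fid <- as.character(raw[[1L]])
  if (anyDuplicated(fid))
    stop("duplicate feature id in ", path, ": ", fid[duplicated(fid)][1L])
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- fid
  ann <- NULL
  if (!is.null(annotations_path))
    ann <- utils::read.delim(annotations_path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
  m <- omics_matrix(values, modality, ann)
  if (is.null(collapse_genes))
    collapse_genes <- modality == "copy_number" && !is.null(ann) &&
      "gene_symbol" %in% names(ann)
  if (collapse_genes) m <- average_by_gene(m)
  m
}

#' Average features sharing a gene symbol
#'
#' Copy-number platforms report many measurements per gene; values mapping to
#' the same gene symbol are averaged (missing values excluded) into one
#' gene-level row. Chromosome and position are taken from the first
#' measurement of each gene.
#'
#' @param m An `omics_matrix` whose annotations include `gene_symbol`.
#' @return An `omics_matrix` with one row per unique gene symbol.
#' @export
average_by_gene <- function(m) {
  ann <- m$annotations
  if (is.null(ann) || !"gene_symbol" %in% names(ann))
    stop("average_by_gene requires gene_symbol annotations")
  g <- as.character(ann$gene_symbol)
  keep <- !is.na(g) & g != ""
  v <- m$values[keep, , drop = FALSE]
  g <- g[keep]
  ug <- unique(g)
  idx <- split(seq_along(g), factor(g, levels = ug))
  out <- matrix(NA_real_, length(ug), ncol(v),
                dimnames = list(ug, colnames(v)))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    if (length(rows) == 1L) out[i, ] <- v[rows, ]
    else out[i, ] <- colMeans(v[rows, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  first <- vapply(idx, `[`, integer(1L), 1L)
  ann2 <- data.frame(feature_id = ug,
                     gene_symbol = ug,
                     stringsAsFactors = FALSE)
  for (col in intersect(c("chromosome", "position"), names(ann)))
    ann2[[col]] <- ann[keep, ][first, col]
  omics_matrix(out, m$modality, ann2)
}

#' Read the clinical table and treatment records
#'
#' `clinical.tsv` has one row per sample with columns `sample_id`, `age`,
#' `stage` (`III`, `IV` or other labels), `batch`, `event_observed` (0/1 or
#' logical), `event_day`, `last_followup_day`; day counts are offsets from
#' surgery (day 0). `treatments.tsv` is long format: `sample_id`, `drug`,
#' `start_day`, `cycles`; samples without any treatment record are allowed.
#'
#' @param path Path to the clinical TSV.
#' @param treatments_path Path to the long-format treatment TSV (optional;
#'   an empty treatment table is used when omitted).
#' @return An object of class `"clinical_table"`: list with `samples` and
#'   `treatments` data frames.
#' @export
read_clinical <- function(path, treatments_path = NULL) {
  samples <- utils::read.delim(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  treatments <- if (is.null(treatments_path)) {
    data.frame(sample_id = character(), drug = character(),
               start_day = numeric(), cycles = numeric(),
               stringsAsFactors = FALSE)
  } else {
    utils::read.delim(treatments_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  clinical_table(samples, treatments)
}

#' Construct and validate a clinical table
#'
#' @param samples Data frame with columns `sample_id`, `age`, `stage`,
#'   `batch`, `event_observed`, `event_day`, `last_followup_day`.
#' @param treatments Data frame with columns `sample_id`, `drug`,
#'   `start_day`, `cycles`.
#' @return An object of class `"clinical_table"`.
#' @export
clinical_table <- function(samples, treatments = NULL) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "age", "stage", "batch", "event_observed",
            "event_day", "last_followup_day")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  samples$event_observed <- as.logical(samples$event_observed)
  bad <- samples$event_observed & (is.na(samples$event_day) | samples$event_day < 0)
  if (any(bad))
    stop("event observed but event_day missing/negative for sample ",
         samples$sample_id[bad][1L])
  bad <- !samples$event_observed &
    (is.na(samples$last_followup_day) | samples$last_followup_day < 0)
  if (any(bad))
    stop("censored sample without nonnegative last_followup_day: ",
         samples$sample_id[bad][1L])
  if (is.null(treatments))
    treatments <- data.frame(sample_id = character(), drug = character(),
                             start_day = numeric(), cycles = numeric(),
                             stringsAsFactors = FALSE)
  treatments <- as.data.frame(treatments)
  needt <- c("sample_id", "drug", "start_day", "cycles")
  if (!all(needt %in% names(treatments)))
    stop("treatment table must have columns ", paste(needt, collapse = ", "))
  unknown <- setdiff(treatments$sample_id, samples$sample_id)
  if (length(unknown))
    stop("treatment record for unknown sample: ", unknown[1L])
  structure(list(samples = samples, treatments = treatments),
            class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("clinical_table: %d samples, %d treatment records\n",
              nrow(x$samples), nrow(x$treatments)))
  invisible(x)
}

#' Align samples across omics matrices and the clinical table
#'
#' Takes the intersection of the sample id sets, in sorted order, and warns
#' about ids dropped from any input. Errors if the intersection is empty.
#'
#' @param matrices List of `omics_matrix` objects (at least one).
#' @param clinical Optional `clinical_table` included in the intersection.
#' @return Sorted character vector of common sample ids.
#' @export
align_samples <- function(matrices, clinical = NULL) {
  if (!length(matrices)) stop("align_samples requires at least one matrix")
  sets <- lapply(matrices, sample_ids)
  if (!is.null(clinical)) sets <- c(sets, list(clinical$samples$sample_id))
  common <- Reduce(intersect, sets)
  if (!length(common)) stop("no samples shared across inputs")
  common <- sort(common)
  dropped <- setdiff(unique(unlist(sets)), common)
  if (length(dropped))
    warning(sprintf("%d sample(s) not present in all inputs were dropped (e.g. %s)",
                    length(dropped), dropped[1L]), call. = FALSE)
  common
}

subset_samples <- function(m, ids) {
  omics_matrix(m$values[, ids, drop = FALSE], m$modality, m$annotations)
}

write_tsv_matrix <- function(values, path, id_col = "feature_id") {
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}
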