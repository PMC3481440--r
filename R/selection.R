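# Progression-free survival and the treatment-based eligibility funnel.

#' Derive progression-free survival from the clinical table
#'
#' PFS is the interval (days) between surgical resection (day 0) and the
#' failure event (progression, recurrence or death); samples without an
#' observed failure contribute their last follow-up day as a right-censored
#' time.
#'
#' @param clinical A `clinical_table`.
#' @return Data frame with columns `sample_id`, `time` (days), `event`
#'   (logical, `TRUE` = failure observed).
#' @export
derive_pfs <- function(clinical) {
  s <- clinical$samples
  time <- ifelse(s$event_observed, s$event_day, s$last_followup_day)
  bad <- is.na(time) | time < 0
  if (any(bad))
    stop("negative or missing PFS time for sample ", s$sample_id[bad][1L])
  data.frame(sample_id = s$sample_id, time = as.numeric(time),
             event = s$event_observed, stringsAsFactors = FALSE)
}

#' Eligibility rules for a uniformly treated cohort
#'
#' Defaults encode the quintessential paclitaxel + carboplatin regimen:
#' advanced-stage (III/IV) disease, both drugs started within 30 days of
#' surgical resection, and at least 4 cycles of each.
#'
#' @param required_drugs Drugs that must each satisfy the timing/cycle rule.
#' @param max_start_delay Latest allowed treatment start (days after surgery).
#' @param min_cycles Minimum recorded cycles per required drug.
#' @param allowed_stages Tumor stages retained.
#' @return A list of class `"selection_rules"`.
#' @export
selection_rules <- function(required_drugs = c("paclitaxel", "carboplatin"),
                            max_start_delay = 30, min_cycles = 4,
                            allowed_stages = c("III", "IV")) {
  stopifnot(max_start_delay >= 0, min_cycles >= 1, length(required_drugs) >= 1)
  structure(list(required_drugs = required_drugs,
                 max_start_delay = max_start_delay,
                 min_cycles = min_cycles,
                 allowed_stages = allowed_stages),
            class = "selection_rules")
}

#' Split a cohort into training, testing and excluded samples
#'
#' A sample is treatment-eligible when its stage is allowed and every
#' required drug has a record started within `max_start_delay` days of
#' surgery with at least `min_cycles` cycles. Eligible samples never given
#' any other drug before their failure (or censoring) day form the training
#' cohort; eligible samples that did receive another drug form the testing
#' cohort, kept apart because the extra treatment may confound survival.
#' Everything else is excluded with a per-sample reason code (`stage`,
#' `missing_<drug>`, `start_delay`, `cycles`).
#'
#' @param clinical A `clinical_table`.
#' @param rules A `selection_rules` object.
#' @return A list of class `"cohort_assignment"`: `training`, `testing`
#'   (character vectors of sample ids) and `excluded` (data frame
#'   `sample_id`, `reason`). The three sets partition the input samples.
#' @export
assign_cohorts <- function(clinical, rules = selection_rules()) {
  s <- clinical$samples
  trt <- clinical$treatments
  pfs <- derive_pfs(clinical)
  horizon <- stats::setNames(pfs$time, pfs$sample_id)

  training <- character()
  testing <- character()
  excl_id <- character()
  excl_reason <- character()

  for (i in seq_len(nrow(s))) {
    id <- s$sample_id[i]
    rec <- trt[trt$sample_id == id, , drop = FALSE]
    if (!(s$stage[i] %in% rules$allowed_stages)) {
      excl_id <- c(excl_id, id); excl_reason <- c(excl_reason, "stage")
      next
    }
    reason <- NULL
    for (drug in rules$required_drugs) {
      dr <- rec[rec$drug == drug, , drop = FALSE]
      if (nrow(dr) == 0L) { reason <- paste0("missing_", drug); break }
      ok <- dr$start_day <= rules$max_start_delay & dr$cycles >= rules$min_cycles
      if (!any(ok)) {
        reason <- if (any(dr$start_day <= rules$max_start_delay))
          "cycles" else "start_delay"
        break
      }
    }
    if (!is.null(reason)) {
      excl_id <- c(excl_id, id); excl_reason <- c(excl_reason, reason)
      next
    }
    other <- rec[!(rec$drug %in% rules$required_drugs), , drop = FALSE]
    if (nrow(other) > 0L && any(other$start_day < horizon[[id]]))
      testing <- c(testing, id)
    else
      training <- c(training, id)
  }
  if (!length(training)) warning("empty training cohort", call. = FALSE)
  if (!length(testing)) warning("empty testing cohort", call. = FALSE)
  structure(list(training = training, testing = testing,
                 excluded = data.frame(sample_id = excl_id,
                                       reason = excl_reason,
                                       stringsAsFactors = FALSE)),
            class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat(sprintf("cohort_assignment: %d training, %d testing, %d excluded\n",
              length(x$training), length(x$testing), nrow(x$excluded)))
  if (nrow(x$excluded)) {
    tab <- table(x$excluded$reason)
    cat("  exclusion reasons:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
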