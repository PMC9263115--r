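#' Dichotomisation thresholds for the endotype classification
#'
#' Builds the three cut-offs used to dichotomise a cohort: a fixed CFVR
#' cut-off (2.5 by convention), and cohort-median cut-offs for the hyperemic
#' velocity and for CCFVR, for which no external reference value exists in
#' heart-transplant patients. Any cut-off can be overridden by a fixed value.
#' "Impaired" always means value <= cut-off.
#'
#' @param metrics Metrics table from [cohort_metrics()] (needs `dpv_h` and
#'   `ccfvr`); may be omitted when both median-based cut-offs are overridden.
#' @param cfvr_cut Fixed CFVR cut-off, default 2.5.
#' @param dpvh_cut Optional fixed DPVh cut-off (cm/s); default `NULL` takes
#'   the cohort median.
#' @param ccfvr_cut Optional fixed CCFVR cut-off (cm/s); default `NULL` takes
#'   the cohort median.
#' @return An object of class `flow_thresholds`: list with `cfvr`, `dpvh`,
#'   `ccfvr` and a `provenance` vector marking each as "fixed" or
#'   "cohort_median".
#' @export
derive_thresholds <- function(metrics = NULL, cfvr_cut = 2.5,
                              dpvh_cut = NULL, ccfvr_cut = NULL) {
  provenance <- c(cfvr = "fixed",
                  dpvh = if (is.null(dpvh_cut)) "cohort_median" else "fixed",
                  ccfvr = if (is.null(ccfvr_cut)) "cohort_median" else "fixed")
  if (is.null(dpvh_cut) || is.null(ccfvr_cut)) {
    if (is.null(metrics) || nrow(metrics) < 2) {
      stop("need a metrics table with at least 2 subjects to derive cohort-median cut-offs")
    }
  }
  if (is.null(dpvh_cut)) {
    dpvh_cut <- stats::median(metrics$dpv_h)
  }
  if (is.null(ccfvr_cut)) {
    ccfvr_cut <- stats::median(metrics$ccfvr)
  }
  cuts <- c(cfvr = cfvr_cut, dpvh = dpvh_cut, ccfvr = ccfvr_cut)
  if (any(!is.finite(cuts)) || any(cuts <= 0)) {
    stop("all cut-offs must be finite and positive")
  }
  structure(list(cfvr = cfvr_cut, dpvh = dpvh_cut, ccfvr = ccfvr_cut,
                 provenance = provenance),
            class = "flow_thresholds")
}

#' @export
print.flow_thresholds <- function(x, ...) {
  cat("Flow dichotomisation thresholds (impaired = value <= cut-off)\n")
  cat(sprintf("  CFVR  <= %-6.3g [%s]\n", x$cfvr, x$provenance[["cfvr"]]))
  cat(sprintf("  DPVh  <= %-6.4g cm/s [%s]\n", x$dpvh, x$provenance[["dpvh"]]))
  cat(sprintf("  CCFVR <= %-6.4g cm/s [%s]\n", x$ccfvr, x$provenance[["ccfvr"]]))
  invisible(x)
}

#' Binary impairment flags for each subject
#'
#' @param metrics Metrics table with `cfvr`, `dpv_h`, `ccfvr`.
#' @param thresholds A [derive_thresholds()] object.
#' @return Data frame of logicals `cmd` (CFVR <= cut-off, coronary
#'   microvascular dysfunction), `low_dpvh`, `low_ccfvr`.
#' @export
flag_subjects <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "flow_thresholds"))
  data.frame(cmd = metrics$cfvr <= thresholds$cfvr,
             low_dpvh = metrics$dpv_h <= thresholds$dpvh,
             low_ccfvr = metrics$ccfvr <= thresholds$ccfvr)
}

#' Primary endotype from the CFVR x DPVh dichotomies
#'
#' Endotype 1: preserved CFVR, impaired DPVh (low resting flow, high basal
#' resistance that drops under adenosine). Endotype 2: both preserved.
#' Endotype 3: both impaired (no vasodilatory headroom). Endotype 4:
#' impaired CFVR, preserved DPVh (flow already high at rest).
#'
#' @param cmd Logical, CFVR impaired.
#' @param low_dpvh Logical, DPVh impaired.
#' @return Factor with levels "1".."4".
#' @export
classify_endotype <- function(cmd, low_dpvh) {
  stopifnot(is.logical(cmd), is.logical(low_dpvh), length(cmd) == length(low_dpvh))
  code <- ifelse(!cmd & low_dpvh, 1L,
          ifelse(!cmd & !low_dpvh, 2L,
          ifelse(cmd & low_dpvh, 3L, 4L)))
  factor(code, levels = 1:4)
}

#' Variant endotype from the CFVR x CCFVR dichotomies
#'
#' The variant scheme replaces DPVh with CCFVR and follows its own
#' numbering, which is not the positional analogue of the primary scheme:
#' 1A = impaired CFVR with preserved CCFVR, 2A = both preserved,
#' 3A = both impaired, 4A = preserved CFVR with impaired CCFVR.
#'
#' @param cmd Logical, CFVR impaired.
#' @param low_ccfvr Logical, CCFVR impaired.
#' @return Factor with levels "1A".."4A".
#' @export
classify_variant <- function(cmd, low_ccfvr) {
  stopifnot(is.logical(cmd), is.logical(low_ccfvr), length(cmd) == length(low_ccfvr))
  code <- ifelse(cmd & !low_ccfvr, "1A",
          ifelse(!cmd & !low_ccfvr, "2A",
          ifelse(cmd & low_ccfvr, "3A", "4A")))
  factor(code, levels = c("1A", "2A", "3A", "4A"))
}

#' Assign endotypes and variant endotypes to a cohort
#'
#' Convenience wrapper: flags every subject against the thresholds and
#' attaches primary and variant endotype labels.
#'
#' @inheritParams flag_subjects
#' @return Data frame with `subject_id` (if present in `metrics`), the three
#'   flags, `endotype` and `variant`.
#' @export
assign_endotypes <- function(metrics, thresholds) {
  flags <- flag_subjects(metrics, thresholds)
  out <- cbind(flags,
               endotype = classify_endotype(flags$cmd, flags$low_dpvh),
               variant = classify_variant(flags$cmd, flags$low_ccfvr))
  if ("subject_id" %in% names(metrics)) {
    out <- cbind(subject_id = metrics$subject_id, out)
  }
  out
}

#' Cross-tabulate the reclassification between endotype schemes
#'
#' Counts subjects, and separately deaths, in each cell of the endotype x
#' variant-endotype table. Row sums recover the primary endotype sizes,
#' column sums the variant sizes, and the death total is conserved by the
#' mapping — the table shows where each scheme's deaths land in the other.
#'
#' @param assignments Output of [assign_endotypes()].
#' @param event Logical or 0/1 vector of death indicators, one per subject.
#' @return Object of class `reclassification_table`: list with integer
#'   matrices `counts` and `deaths` (rows endotype 1-4, columns 1A-4A).
#' @export
reclassification_table <- function(assignments, event) {
  if (anyNA(assignments$endotype) || anyNA(assignments$variant)) {
    stop("every subject needs both an endotype and a variant label")
  }
  event <- as.logical(event)
  if (length(event) != nrow(assignments) || anyNA(event)) {
    stop("need one non-missing death indicator per subject")
  }
  counts <- table(endotype = assignments$endotype, variant = assignments$variant)
  deaths <- table(endotype = assignments$endotype[event],
                  variant = assignments$variant[event])
  structure(list(counts = unclass(counts), deaths = unclass(deaths),
                 n = nrow(assignments), n_deaths = sum(event)),
            class = "reclassification_table")
}

#' @export
print.reclassification_table <- function(x, ...) {
  cat("Endotype -> variant-endotype reclassification (", x$n, " subjects, ",
      x$n_deaths, " deaths)\n\nSubjects:\n", sep = "")
  print(x$counts)
  cat("\nDeaths:\n")
  print(x$deaths)
  invisible(x)
}
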