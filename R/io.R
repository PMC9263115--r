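#' Cohort table schema
#'
#' Column names of the delimiter-separated cohort table. Units are fixed:
#' velocities cm/s, pressures mmHg, heart rates bpm, follow-up years,
#' ischemic time minutes.
#'
#' @return List with `required` and `optional` column name vectors.
#' @export
cohort_schema <- function() {
  list(required = c("subject_id", "group", "dpv_r", "dpv_h",
                    "sap_r", "dap_r", "sap_h", "dap_h", "hr_r", "hr_h"),
       optional = c("time_years", "event", "age_at_ht", "donor_age",
                    "ischemic_time_min", "cav_onset", "cav_grade",
                    "sex_recipient", "sex_donor", "diabetes", "ihd_pre_ht",
                    "trs", "rs_1st_year", "sev_trs", "sev_rs_1st_year",
                    "lvef"))
}

#' Read and validate a cohort table
#'
#' Reads a delimiter-separated cohort file, checks the header against the
#' schema and validates each row's vitals (positive velocities and heart
#' rates, systolic above diastolic pressure in each condition). Invalid rows
#' abort the read with their line numbers; unknown columns are kept with a
#' warning; valid rows are never silently dropped.
#'
#' @param path Path to the file.
#' @param sep Field delimiter, default comma.
#' @return Validated data frame.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_cohort(df)
}

#' Validate an in-memory cohort table
#'
#' @param df Data frame in the cohort schema.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_cohort <- function(df) {
  schema <- cohort_schema()
  missing_req <- setdiff(schema$required, names(df))
  if (length(missing_req)) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  }
  unknown <- setdiff(names(df), c(schema$required, schema$optional))
  if (length(unknown)) {
    warning("unknown column(s) kept as-is: ", paste(unknown, collapse = ", "))
  }
  bad_group <- !df$group %in% c("ht", "control")
  if (any(bad_group)) {
    stop("invalid group (must be 'ht' or 'control') at data line(s): ",
         paste(which(bad_group), collapse = ", "))
  }
  problems <- character(0)
  check <- function(cond, what) {
    bad <- which(!is.na(cond) & cond)
    if (length(bad)) {
      problems <<- c(problems,
                     paste0(what, " at data line(s) ",
                            paste(bad, collapse = ", ")))
    }
  }
  check(df$dpv_r <= 0, "non-positive dpv_r")
  check(df$dpv_h <= 0, "non-positive dpv_h")
  check(df$sap_r <= df$dap_r | df$dap_r <= 0, "need sap_r > dap_r > 0")
  check(df$sap_h <= df$dap_h | df$dap_h <= 0, "need sap_h > dap_h > 0")
  check(df$hr_r <= 0, "non-positive hr_r")
  check(df$hr_h <= 0, "non-positive hr_h")
  if ("time_years" %in% names(df)) check(df$time_years <= 0,
                                         "non-positive time_years")
  for (col in c("dpv_r", "dpv_h", "sap_r", "dap_r", "sap_h", "dap_h",
                "hr_r", "hr_h")) {
    check(is.na(df[[col]]), paste0("missing ", col))
  }
  if (length(problems)) {
    stop("invalid cohort rows:\n  ", paste(problems, collapse = "\n  "))
  }
  df
}

#' Write a cohort table
#'
#' @param df Cohort data frame.
#' @param path Output path.
#' @param sep Field delimiter, default comma.
#' @export
write_cohort <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Median (Q1-Q3) summary of flow metrics by group
#'
#' The descriptive report surface: per-group medians with quartiles of the
#' hemodynamic indices, in the conventional reporting precision (one decimal
#' for velocities and ratios, two for resistances).
#'
#' @param metrics Metrics table from [cohort_metrics()].
#' @param group Grouping vector (e.g. `"control"`/`"ht"`, or endotype).
#' @return Data frame: one row per metric, one column per group with
#'   "median (Q1-Q3)" strings.
#' @export
summarize_flow <- function(metrics, group) {
  vars <- c(dpv_r = 1, dpv_h = 1, cfvr = 1, bmr = 2, hmr = 2, ari = 2,
            rpcfvr = 1, delta_dpv_abs = 1, delta_dpv_pct = 0, ccfvr = 1)
  group <- factor(group)
  fmt <- function(x, d) {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
    sprintf("%.*f (%.*f-%.*f)", d, q[1], d, q[2], d, q[3])
  }
  out <- data.frame(metric = names(vars))
  for (g in levels(group)) {
    sub <- metrics[group == g, , drop = FALSE]
    out[[g]] <- vapply(seq_along(vars), function(i) {
      fmt(sub[[names(vars)[i]]], vars[i])
    }, character(1))
  }
  out
}

#' Run the full coronary-flow analysis pipeline
#'
#' Executes the stages in order: hemodynamic metrics, threshold derivation,
#' endotype and variant assignment, descriptive summaries, death
#' reclassification, survival analysis (Kaplan-Meier by endotype, log-rank,
#' univariable screen, multivariable models with each flow marker added
#' separately, model comparison), and, when repeated measurements are
#' supplied, the reproducibility report. Stages needing survival columns
#' are skipped with a notice when those columns are absent.
#'
#' @param cohort Cohort data frame in the schema, or `NULL` to simulate one
#'   (together with controls) from `config` and `seed`.
#' @param config [generator_config()] used when simulating.
#' @param seed Integer seed for simulation; logged in the result.
#' @param out_dir Optional directory: when given, every result table is
#'   written there as a CSV file.
#' @param repeated Optional data frame/list with elements or columns
#'   `first` and `second` of repeated CFVR readings.
#' @param base_covariates Covariates of the base prognostic model (defaults
#'   to the clinical set: age at transplant, donor age, ischemic time, CAV
#'   onset).
#' @return List of class `flow_pipeline` with elements `cohort`, `metrics`,
#'   `thresholds`, `assignments`, `flow_by_group`, `flow_by_endotype`,
#'   `reclassification`, `survival` (km fit, log-rank, screen, model
#'   comparison) and `agreement`, plus `seed`.
#' @export
run_pipeline <- function(cohort = NULL, config = generator_config(),
                         seed = NULL, out_dir = NULL, repeated = NULL,
                         base_covariates = c("age_at_ht", "donor_age",
                                             "ischemic_time_min",
                                             "cav_onset")) {
  if (is.null(cohort)) {
    ht <- simulate_ht_cohort(config, seed = seed)
    ctrl <- simulate_controls(config = config)
    common <- intersect(names(ht), names(ctrl))
    extra <- setdiff(names(ht), names(ctrl))
    for (col in extra) ctrl[[col]] <- NA
    cohort <- rbind(ht[c(common, extra)], ctrl[c(common, extra)])
  }
  cohort <- validate_cohort(cohort)
  metrics <- cohort_metrics(cohort)
  ht_idx <- cohort$group == "ht"
  # median cut-offs come from the study (HT) group; fall back to the whole
  # table when the input holds no HT subjects
  thr_rows <- if (any(ht_idx)) metrics[ht_idx, , drop = FALSE] else metrics
  thresholds <- derive_thresholds(thr_rows)
  assignments <- assign_endotypes(metrics, thresholds)
  res <- list(cohort = cohort, metrics = metrics, thresholds = thresholds,
              assignments = assignments, seed = seed)
  res$flow_by_group <- summarize_flow(metrics, cohort$group)
  if (any(ht_idx)) {
    res$flow_by_endotype <- summarize_flow(metrics[ht_idx, , drop = FALSE],
                                           assignments$endotype[ht_idx])
  }
  have_survival <- all(c("time_years", "event") %in% names(cohort)) &&
    any(!is.na(cohort$time_years[ht_idx]))
  if (have_survival) {
    ht <- cbind(cohort[ht_idx, , drop = FALSE],
                assignments[ht_idx, c("cmd", "low_dpvh", "low_ccfvr",
                                      "endotype", "variant")],
                metrics[ht_idx, c("cfvr", "ccfvr"), drop = FALSE])
    res$reclassification <- reclassification_table(
      assignments[ht_idx, , drop = FALSE], ht$event)
    entry <- rep(min(5, min(ht$time_years) * 0.99), nrow(ht))
    res$survival <- list(
      km = km_curves(ht$time_years, ht$event, ht$endotype, entry = entry),
      logrank = logrank_test(ht$time_years, ht$event, ht$endotype,
                             entry = entry),
      screen = tryCatch(
        univariable_screen(ht, c(base_covariates, "cmd", "low_dpvh",
                                 "low_ccfvr")),
        warning = function(w) suppressWarnings(
          univariable_screen(ht, c(base_covariates, "cmd", "low_dpvh",
                                   "low_ccfvr")))),
      comparison = model_comparison(ht, base_covariates,
                                    c("cmd", "low_dpvh", "low_ccfvr"))
    )
  } else {
    message("survival columns absent or empty: survival stage skipped")
  }
  if (!is.null(repeated)) {
    res$agreement <- agreement_report(repeated$first, repeated$second)
  }
  class(res) <- "flow_pipeline"
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' Write pipeline result tables to a directory
#'
#' @param res A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(res$metrics, "metrics")
  wr(res$assignments, "assignments")
  wr(res$flow_by_group, "flow_by_group")
  if (!is.null(res$flow_by_endotype)) wr(res$flow_by_endotype, "flow_by_endotype")
  wr(data.frame(cutoff = c("cfvr", "dpvh", "ccfvr"),
                value = c(res$thresholds$cfvr, res$thresholds$dpvh,
                          res$thresholds$ccfvr),
                provenance = unname(res$thresholds$provenance)),
     "thresholds")
  if (!is.null(res$reclassification)) {
    wr(as.data.frame(res$reclassification$counts), "reclassification_counts")
    wr(as.data.frame(res$reclassification$deaths), "reclassification_deaths")
  }
  if (!is.null(res$survival)) {
    wr(res$survival$screen, "univariable_screen")
    wr(as.data.frame(res$survival$comparison), "model_comparison")
  }
  if (!is.null(res$seed)) {
    writeLines(paste("seed:", res$seed), file.path(out_dir, "seed.txt"))
  }
  invisible(out_dir)
}

#' @export
print.flow_pipeline <- function(x, ...) {
  n_ht <- sum(x$cohort$group == "ht")
  n_ctrl <- sum(x$cohort$group == "control")
  cat(sprintf("Coronary-flow pipeline: %d HT subjects, %d controls\n",
              n_ht, n_ctrl))
  print(x$thresholds)
  cat("\nEndotype sizes (HT):\n")
  print(table(x$assignments$endotype[x$cohort$group == "ht"]))
  if (!is.null(x$survival)) {
    cat(sprintf("\nLog-rank across endotypes: chi-square %.2f (df %d), p = %.3g\n",
                x$survival$logrank$statistic, x$survival$logrank$df,
                x$survival$logrank$p_value))
    print(x$survival$comparison)
  }
  if (!is.null(x$agreement)) print(x$agreement)
  invisible(x)
}
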