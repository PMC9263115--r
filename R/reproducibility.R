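#' Regression agreement between repeated measurements
#'
#' Agreement of two CFVR readings per subject (same observer an hour apart,
#' or two observers) summarised by the Pearson correlation and the residual
#' standard error (SEE) of the least-squares line of the second reading on
#' the first.
#'
#' @param first,second Paired readings, equal length >= 3, finite.
#' @return List with `r`, `see`, `intercept`, `slope`, `n`.
#' @export
regression_agreement <- function(first, second) {
  check_paired_measurements(first, second)
  if (stats::var(first) == 0 || stats::var(second) == 0) {
    stop("both measurement series need positive variance")
  }
  fit <- stats::lm(second ~ first)
  # residual SE computed directly: summary.lm warns on a perfect fit
  see <- sqrt(sum(stats::residuals(fit)^2) / (length(first) - 2))
  list(r = stats::cor(first, second),
       see = see,
       intercept = unname(coef(fit)[1]),
       slope = unname(coef(fit)[2]),
       n = length(first))
}

#' Bland-Altman limits of agreement
#'
#' Mean difference (second minus first) with 95% limits of agreement
#' d_bar +/- 1.96 SD(d), and confidence intervals for the mean difference
#' (SE = s/sqrt(n)) and for each limit (SE = s sqrt(3/n)), using the t
#' distribution with n - 1 degrees of freedom.
#'
#' @inheritParams regression_agreement
#' @param conf Confidence level for the interval estimates, default 0.95.
#' @return List with `mean_diff`, `sd_diff`, `lower`, `upper` (limits of
#'   agreement), `mean_diff_ci`, `lower_ci`, `upper_ci` (length-2 vectors),
#'   `n`.
#' @export
bland_altman <- function(first, second, conf = 0.95) {
  check_paired_measurements(first, second)
  d <- second - first
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  se_mean <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  list(mean_diff = m, sd_diff = s, lower = lower, upper = upper,
       mean_diff_ci = c(m - tq * se_mean, m + tq * se_mean),
       lower_ci = c(lower - tq * se_loa, lower + tq * se_loa),
       upper_ci = c(upper - tq * se_loa, upper + tq * se_loa),
       n = n)
}

#' Intraclass correlation coefficient for two measurement sessions
#'
#' Single-measurement ICC from the two-way model with subjects as random
#' rows and the two sessions/raters as fixed columns. The default
#' "agreement" form (absolute agreement, ICC(A,1)) penalises a systematic
#' offset between sessions; the "consistency" form (ICC(C,1)) does not.
#' Values of 0.81-1.0 are conventionally read as satisfactory
#' reproducibility.
#'
#' @inheritParams regression_agreement
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return List with `icc`, `type`, `satisfactory` (icc >= 0.81), and the
#'   mean squares `ms_rows`, `ms_cols`, `ms_error`.
#' @export
icc_agreement <- function(first, second, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  check_paired_measurements(first, second)
  n <- length(first)
  k <- 2
  x <- cbind(first, second)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  icc <- if (type == "agreement") {
    (ms_rows - ms_error) /
      (ms_rows + (k - 1) * ms_error + k * (ms_cols - ms_error) / n)
  } else {
    (ms_rows - ms_error) / (ms_rows + (k - 1) * ms_error)
  }
  list(icc = icc, type = type, satisfactory = is.finite(icc) && icc >= 0.81,
       ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error)
}

#' Full measurement-agreement report
#'
#' Bundles the regression agreement, Bland-Altman limits and ICC for one
#' pair of repeated measurement series.
#'
#' @inheritParams regression_agreement
#' @param label Optional label (e.g. "intraobserver").
#' @return Object of class `agreement_report`.
#' @export
agreement_report <- function(first, second, label = "agreement") {
  structure(list(label = label,
                 regression = regression_agreement(first, second),
                 bland_altman = bland_altman(first, second),
                 icc = icc_agreement(first, second)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  r <- x$regression; b <- x$bland_altman; i <- x$icc
  cat(sprintf("Reproducibility (%s, n = %d)\n", x$label, r$n))
  cat(sprintf("  r = %.2f, SEE = %.2f\n", r$r, r$see))
  cat(sprintf("  mean difference %.3f; limits of agreement %+.2f (%.2f to %.2f) and %+.2f (%.2f to %.2f)\n",
              b$mean_diff, b$upper, b$upper_ci[1], b$upper_ci[2],
              b$lower, b$lower_ci[1], b$lower_ci[2]))
  cat(sprintf("  ICC = %.3f (%s)%s\n", i$icc, i$type,
              if (i$satisfactory) " - satisfactory" else ""))
  invisible(x)
}

check_paired_measurements <- function(first, second) {
  stopifnot(is.numeric(first), is.numeric(second))
  if (length(first) != length(second)) {
    stop("measurement series must have equal length")
  }
  if (length(first) < 3) stop("need at least 3 paired measurements")
  if (!all(is.finite(first)) || !all(is.finite(second))) {
    stop("measurement series must be finite")
  }
  invisible(TRUE)
}
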