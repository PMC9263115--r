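#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimate of event-free survival, optionally left-truncated
#' (subjects enter the risk set only after a delayed-entry time, as with a
#' cohort enrolled conditional on 5-year survival).
#'
#' @param time Follow-up time, years; positive.
#' @param event Event indicator (1/TRUE = death).
#' @param group Optional grouping factor (e.g. endotype); default one group.
#' @param entry Optional delayed-entry time (single value or per-subject
#'   vector); must be strictly below each subject's `time`.
#' @return A [survival::survfit] object.
#' @export
km_curves <- function(time, event, group = NULL, entry = NULL) {
  d <- check_survival_records(time, event, group, entry)
  if (is.null(d$group)) d$group <- factor(rep("all", length(d$time)))
  if (any(table(d$group) < 1)) stop("every group needs at least one record")
  if (is.null(d$entry)) {
    survival::survfit(survival::Surv(d$time, d$event) ~ d$group)
  } else {
    survival::survfit(survival::Surv(d$entry, d$time, d$event) ~ d$group)
  }
}

#' Log-rank comparison of survival between groups
#'
#' @inheritParams km_curves
#' @return List with `statistic` (chi-square), `df` (groups - 1) and
#'   `p_value`.
#' @export
logrank_test <- function(time, event, group, entry = NULL) {
  d <- check_survival_records(time, event, group, entry)
  if (nlevels(droplevels(factor(d$group))) < 2) {
    stop("log-rank test needs at least 2 groups")
  }
  # a delayed entry common to all subjects leaves every log-rank risk set
  # unchanged (no one is at risk, and no event occurs, before it), so the
  # standard two-column form applies; heterogeneous entry would not reduce
  if (!is.null(d$entry) && length(unique(d$entry)) > 1) {
    stop("log-rank with subject-specific delayed entry is not supported")
  }
  fit <- survival::survdiff(survival::Surv(d$time, d$event) ~ d$group)
  df <- length(fit$n) - 1
  list(statistic = unname(fit$chisq), df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood with Breslow handling of tied event
#' times. Non-convergence and separation (coefficients running to infinity)
#' raise errors rather than returning unstable estimates.
#'
#' @param data Data frame holding the survival columns and covariates.
#' @param covariates Character vector of covariate column names.
#' @param time,event,entry Column names of the follow-up time, event
#'   indicator and (optional) delayed-entry time; defaults `"time_years"`,
#'   `"event"`, `NULL`.
#' @param conf_level Confidence level for hazard-ratio intervals, default 0.95.
#' @return Object of class `flow_cox`: list with `summary` (data frame of
#'   term, coef, hr, ci bounds, p), `loglik` (vector: null model, fitted),
#'   `concordance`, `n`, `n_events`, `covariates` and the underlying
#'   [survival::coxph] `model`.
#' @export
cox_fit <- function(data, covariates, time = "time_years", event = "event",
                    entry = NULL, conf_level = 0.95) {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  missing_cols <- setdiff(c(time, event, entry, covariates), names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  }
  if (sum(data[[event]]) < 1) stop("need at least one event to fit a Cox model")
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.character(v)) v <- factor(v)
    if (length(unique(v[!is.na(v)])) < 2) {
      stop("covariate '", cv, "' is constant across subjects")
    }
  }
  surv <- if (is.null(entry)) {
    sprintf("survival::Surv(%s, %s)", time, event)
  } else {
    sprintf("survival::Surv(%s, %s, %s)", entry, time, event)
  }
  fml <- stats::as.formula(paste(surv, "~", paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "breslow"),
    warning = function(w) {
      if (grepl("did not converge|infinite|out of iterations|beta may be infinite",
                conditionMessage(w))) {
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 20)) {
    stop("Cox fit failed: coefficient estimate diverged (likely separation)")
  }
  s <- summary(fit, conf.int = conf_level)
  ci <- s$conf.int
  smry <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_lower = ci[, 3],
    ci_upper = ci[, 4],
    p_value = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(list(summary = smry,
                 loglik = fit$loglik,
                 concordance = unname(s$concordance["C"]),
                 n = s$n, n_events = s$nevent,
                 covariates = covariates,
                 time = time, event = event, entry = entry,
                 conf_level = conf_level,
                 model = fit),
            class = "flow_cox")
}

#' @export
print.flow_cox <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (Breslow ties): %d subjects, %d events\n",
              x$n, x$n_events))
  smry <- x$summary
  smry$hr <- round(smry$hr, digits)
  smry$ci_lower <- round(smry$ci_lower, digits)
  smry$ci_upper <- round(smry$ci_upper, digits)
  smry$p_value <- signif(smry$p_value, 2)
  print(smry[c("term", "hr", "ci_lower", "ci_upper", "p_value")],
        row.names = FALSE)
  cat(sprintf("Concordance %.3f, log-likelihood %.2f\n",
              x$concordance, x$loglik[2]))
  invisible(x)
}

#' Linear predictor (risk score) of a Cox fit
#'
#' @param object A [cox_fit()] object.
#' @param newdata Optional data frame; defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of linear predictors (higher = higher hazard).
#' @export
predict.flow_cox <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    unname(stats::predict(object$model, type = "lp"))
  } else {
    unname(stats::predict(object$model, newdata = newdata, type = "lp"))
  }
}

#' Univariable Cox screen
#'
#' Fits each candidate covariate alone and flags those reaching the
#' screening threshold (p < alpha, default 0.10) for inclusion in a
#' multivariable model. Candidates whose single-covariate fit fails (e.g.
#' separation) are recorded with `NA` and never selected.
#'
#' @inheritParams cox_fit
#' @param candidates Character vector of candidate covariate names.
#' @param alpha Screening significance level in (0, 1), default 0.10.
#' @return Data frame with one row per candidate in input order: `term`,
#'   `hr`, `ci_lower`, `ci_upper`, `p_value`, `selected`. The selected names
#'   are in `attr(, "selected")`. Warns when nothing is selected.
#' @export
univariable_screen <- function(data, candidates, alpha = 0.10,
                               time = "time_years", event = "event",
                               entry = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  rows <- lapply(candidates, function(cv) {
    fit <- tryCatch(cox_fit(data, cv, time = time, event = event, entry = entry),
                    error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(term = cv, hr = NA_real_, ci_lower = NA_real_,
                 ci_upper = NA_real_, p_value = NA_real_)
    } else {
      fit$summary[1, c("term", "hr", "ci_lower", "ci_upper", "p_value")]
    }
  })
  out <- do.call(rbind, rows)
  out$selected <- !is.na(out$p_value) & out$p_value < alpha
  selected <- candidates[out$selected]
  if (!length(selected)) {
    warning("no candidate reached p < ", alpha,
            "; the multivariable step should be skipped")
  }
  attr(out, "selected") <- selected
  out
}

#' Harrell's concordance index
#'
#' Probability that, of two comparable subjects, the one with the higher
#' risk score fails first. Pairs are usable when censoring leaves their
#' event ordering determinable; tied risk scores count one half.
#'
#' @param risk Numeric risk scores, higher = predicted earlier failure.
#' @param time Follow-up times.
#' @param event Event indicators.
#' @return Concordance in [0, 1].
#' @export
harrell_c <- function(risk, time, event) {
  d <- check_survival_records(time, event)
  stopifnot(length(risk) == length(d$time), all(is.finite(risk)))
  fit <- survival::concordance(survival::Surv(d$time, d$event) ~ risk,
                               reverse = TRUE)
  unname(fit$concordance)
}

#' Likelihood-ratio test between nested Cox models
#'
#' Tests whether covariates added to a base model improve fit: statistic
#' 2 (LL_extended - LL_base), chi-square with df = number of added
#' coefficients. Both models must be fitted on the same records.
#'
#' @param base,extended [cox_fit()] objects; `extended` must nest `base`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(base, extended) {
  stopifnot(inherits(base, "flow_cox"), inherits(extended, "flow_cox"))
  if (!all(base$covariates %in% extended$covariates)) {
    stop("models are not nested: base covariates must be a subset of extended")
  }
  if (base$n != extended$n || base$n_events != extended$n_events) {
    stop("models were not fitted on identical records")
  }
  df <- length(coef(extended$model)) - length(coef(base$model))
  if (df < 0) stop("extended model has fewer coefficients than base")
  stat <- 2 * (extended$loglik[2] - base$loglik[2])
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Continuous net reclassification improvement
#'
#' Compares predicted risks under a base and an extended model:
#' NRI = [P(up | event) - P(down | event)] +
#' [P(down | non-event) - P(up | non-event)], where "up"/"down" is any
#' increase/decrease of the predicted risk in the extended model. Ranges
#' over [-2, 2]; 0 means no net improvement.
#'
#' @param base_risk,ext_risk Paired risk estimates per subject (any
#'   monotone risk scale; only the direction of change is used).
#' @param event Event indicators.
#' @return List with `nri` and its `event` and `nonevent` components.
#' @export
continuous_nri <- function(base_risk, ext_risk, event) {
  stopifnot(length(base_risk) == length(ext_risk),
            length(event) == length(base_risk))
  event <- as.logical(event)
  if (!any(event) || all(event)) {
    stop("continuous NRI needs both events and non-events")
  }
  change <- sign(ext_risk - base_risk)
  ev_comp <- mean(change[event] > 0) - mean(change[event] < 0)
  ne_comp <- mean(change[!event] < 0) - mean(change[!event] > 0)
  list(nri = ev_comp + ne_comp, event = ev_comp, nonevent = ne_comp)
}

#' Compare prognostic models built on a common clinical base
#'
#' Fits a base Cox model and one extended model per added marker (each
#' marker added separately, never jointly), and reports the discrimination
#' and reclassification gain of each extension: Harrell's C, the
#' likelihood-ratio test against the base model, and the continuous NRI of
#' the extended risk scores.
#'
#' @inheritParams cox_fit
#' @param base_covariates Covariates of the base (clinical) model.
#' @param added_markers Character vector; each entry is added alone.
#' @return Object of class `flow_model_comparison`: data frame with one row
#'   for the base model and one per extension (`model`, `c_index`,
#'   `loglik`, `lrt_chisq`, `lrt_p`, `nri`), with the fitted models in
#'   `attr(, "fits")`.
#' @export
model_comparison <- function(data, base_covariates, added_markers,
                             time = "time_years", event = "event",
                             entry = NULL) {
  base <- cox_fit(data, base_covariates, time = time, event = event,
                  entry = entry)
  base_risk <- predict(base)
  ev <- data[[event]]
  rows <- data.frame(model = "base", c_index = base$concordance,
                     loglik = base$loglik[2], lrt_chisq = NA_real_,
                     lrt_p = NA_real_, nri = NA_real_)
  fits <- list(base = base)
  for (mk in added_markers) {
    ext <- cox_fit(data, c(base_covariates, mk), time = time, event = event,
                   entry = entry)
    lrt <- likelihood_ratio_test(base, ext)
    nri <- continuous_nri(base_risk, predict(ext), ev)
    rows <- rbind(rows, data.frame(
      model = paste0("base + ", mk), c_index = ext$concordance,
      loglik = ext$loglik[2], lrt_chisq = lrt$statistic, lrt_p = lrt$p_value,
      nri = nri$nri))
    fits[[mk]] <- ext
  }
  attr(rows, "fits") <- fits
  class(rows) <- c("flow_model_comparison", class(rows))
  rows
}

#' @export
print.flow_model_comparison <- function(x, ...) {
  cat("Prognostic model comparison (each marker added to the base separately)\n")
  y <- as.data.frame(x)
  y$c_index <- round(y$c_index, 3)
  y$loglik <- round(y$loglik, 2)
  y$lrt_chisq <- round(y$lrt_chisq, 2)
  y$lrt_p <- signif(y$lrt_p, 2)
  y$nri <- round(y$nri, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

# shared validation of survival records
check_survival_records <- function(time, event, group = NULL, entry = NULL) {
  stopifnot(is.numeric(time))
  event <- as.numeric(as.logical(event))
  if (length(event) != length(time) || anyNA(time) || anyNA(event)) {
    stop("need matched, non-missing time and event vectors")
  }
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!is.null(entry)) {
    if (length(entry) == 1) entry <- rep(entry, length(time))
    if (any(entry >= time)) {
      stop("delayed-entry time must be below each subject's follow-up time")
    }
  }
  if (!is.null(group)) {
    group <- factor(group)
    if (length(group) != length(time)) stop("grouping must match records")
  }
  list(time = time, event = event, group = group, entry = entry)
}
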