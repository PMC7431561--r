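#' ROC curve and AUC for a score against a binary outcome
#'
#' The curve is traced over all distinct score thresholds with the
#' classification rule "score >= threshold predicts the event"; AUC is the
#' trapezoidal area, which equals the tie-corrected Mann-Whitney concordance
#' probability P(score_event > score_no_event) + 0.5 P(tie).
#'
#' @param scores numeric scores, one per subject.
#' @param outcome logical or 0/1 event indicator (1 = event, e.g. death).
#' @return A list of class `roc_result`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  if (length(scores) != length(outcome) || anyNA(scores) || anyNA(outcome))
    stop_input("scores and outcome must be same-length and complete")
  if (!any(outcome) || all(outcome))
    stop_input("both outcome classes must be present")
  thr <- sort(unique(scores))
  n_pos <- sum(outcome); n_neg <- sum(!outcome)
  tpr <- vapply(thr, function(t) sum(scores >= t & outcome) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !outcome) / n_neg,
                numeric(1))
  pts <- data.frame(threshold = c(-Inf, thr, Inf),
                    fpr = c(1, fpr, 0), tpr = c(1, tpr, 0))
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' Choose a dichotomization cutoff for a prognostic score
#'
#' Candidate cutoffs are the midpoints between adjacent distinct scores.
#' Methods: `"balanced"` minimizes |sensitivity - specificity| (the manual
#' sensitivity-specificity balance), `"youden"` maximizes
#' sensitivity + specificity - 1, and `"logrank_scan"` picks the cutoff
#' whose two groups have the smallest log-rank p (requires `times` and
#' `events`). Ties break toward the lower cutoff. Classification is
#' "score >= cutoff is the high group"; `direction` controls which group is
#' the predicted event: `"auto"` (default) predicts the event for low scores
#' when AUC < 0.5 (a protective marker), for high scores otherwise.
#'
#' @param scores numeric scores.
#' @param outcome binary event indicator.
#' @param method `"balanced"`, `"youden"` or `"logrank_scan"`.
#' @param times,events survival input for `"logrank_scan"`.
#' @param direction `"auto"`, `">="` (high score predicts event) or `"<"`.
#' @return A list of class `cutoff_result`: `cutoff`, `sensitivity`,
#'   `specificity`, `method`, `direction`.
#' @export
select_cutoff <- function(scores, outcome,
                          method = c("balanced", "youden", "logrank_scan"),
                          times = NULL, events = NULL,
                          direction = c("auto", ">=", "<")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  outcome <- as.logical(outcome)
  if (length(unique(scores)) < 2L)
    stop_input("all scores are equal: no cutoff exists")
  if (!any(outcome) || all(outcome))
    stop_input("both outcome classes must be present")
  s <- sort(unique(scores))
  cand <- (head(s, -1) + s[-1]) / 2
  if (direction == "auto")
    direction <- if (roc_curve(scores, outcome)$auc < 0.5) "<" else ">="

  sens_spec <- function(c) {
    pred <- if (direction == ">=") scores >= c else scores < c
    c(sens = sum(pred & outcome) / sum(outcome),
      spec = sum(!pred & !outcome) / sum(!outcome))
  }
  if (method == "logrank_scan") {
    if (is.null(times) || is.null(events))
      stop_input("logrank_scan requires times and events")
    crit <- vapply(cand, function(c) {
      grp <- scores >= c
      if (!any(grp) || all(grp)) return(Inf)
      logrank(times, events, grp)$p_value
    }, numeric(1))
    best <- cand[which.min(crit)]   # which.min ties -> first = lower cutoff
  } else {
    ss <- vapply(cand, sens_spec, numeric(2))
    crit <- if (method == "balanced") abs(ss["sens", ] - ss["spec", ])
            else -(ss["sens", ] + ss["spec", ] - 1)
    best <- cand[which.min(crit)]
  }
  ss <- sens_spec(best)
  structure(list(cutoff = best, sensitivity = unname(ss["sens"]),
                 specificity = unname(ss["spec"]), method = method,
                 direction = direction), class = "cutoff_result")
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] (events precede censorings at tied times, the
#' standard convention) and exposes the curve with a median (smallest time
#' at which S(t) drops to 0.5 or below; `NA` when never reached) and a step
#' lookup `surv_at`, so that `surv_at(60)` is the 5-year survival estimate
#' when times are in months.
#'
#' @param times nonnegative follow-up times (months).
#' @param events event indicator (1/TRUE = death, 0/FALSE = censored).
#' @return A list of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `median`, `surv_at` (function), `degenerate`
#'   (TRUE when the input carries no events).
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop_input("negative survival times")
  if (length(times) < 1L || length(times) != length(events))
    stop_input("times and events must be same-length, n >= 1")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]]
         else NA_real_
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, median = med,
                 surv_at = function(t) sf(t),
                 degenerate = sum(events) == 0L),
            class = "km_curve")
}

#' Log-rank comparison of two or more survival curves
#'
#' Standard log-rank test (hypergeometric variance at each distinct event
#' time, via [survival::survdiff()]); p from chi-square with k-1 degrees of
#' freedom.
#'
#' @param times,events survival input.
#' @param group group labels (factor-like), k >= 2 non-empty groups.
#' @return A list of class `logrank_result`: `statistic`, `df`, `p_value`,
#'   `n_per_group`, `observed`, `expected`.
#' @export
logrank <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop_input("at least two groups required")
  if (any(table(group) == 0L)) stop_input("a group has zero subjects")
  events <- as.integer(as.logical(events))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n_per_group = as.vector(table(group)),
                 observed = as.vector(sd$obs),
                 expected = as.vector(sd$exp)),
            class = "logrank_result")
}

#' Multivariate Cox proportional-hazards model
#'
#' Fits [survival::coxph()] on a patient cohort, Efron tie handling by
#' default, and reports per-coefficient hazard ratios with Wald 95%
#' confidence intervals (computed on the log-hazard scale and
#' exponentiated). Categorical covariates are expanded against their first
#' factor level as reference; for the standard cohort columns the references
#' are female sex, early stage, well-differentiated grade and the low score
#' group.
#'
#' @param cohort data.frame with columns `time_months`, `event`, and the
#'   requested covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A list of class `cox_result`: `table` (data.frame `term`,
#'   `hazard_ratio`, `ci95_low`, `ci95_high`, `p_value`), `ties`,
#'   `iterations`, `converged`, `flags`, `n`, `n_events`, `fit`.
#' @export
cox_ph <- function(cohort, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!all(c("time_months", "event") %in% names(cohort)))
    stop_input("cohort must have time_months and event columns")
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop_input("covariates not in cohort: ",
               paste(missing_cov, collapse = ", "))
  ev <- as.integer(as.logical(cohort$event))
  if (sum(ev) == 0L) stop_input("no events in cohort")
  flags <- character(0)
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, ev) ~",
    paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  tab <- data.frame(term = names(beta),
                    hazard_ratio = exp(beta),
                    ci95_low = exp(beta - 1.959964 * se),
                    ci95_high = exp(beta + 1.959964 * se),
                    p_value = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  converged <- fit$iter < 50 && !any(grepl("converge|infinite", flags))
  if (!converged) flags <- c(flags, "model did not converge cleanly")
  structure(list(table = tab, ties = ties, iterations = fit$iter,
                 converged = converged, flags = flags,
                 n = fit$n, n_events = fit$nevent, fit = fit),
            class = "cox_result")
}
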