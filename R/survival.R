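# Survival-biomarker engine, from first principles: empirical ROC with
# DeLong CI, Youden-index cutoff with Wilson CIs, Kaplan-Meier product-limit
# estimator, log-rank (Mantel-Cox) test, and univariate Cox partial
# likelihood with Efron tie handling. Orientation throughout: higher
# biomarker values predict the positive class (survivors), with the
# classification rule "value >= cutoff => predicted positive".

#' Dichotomize survival at five years
#'
#' Patients surviving at least 60 months (event or censored) are survivors;
#' patients who died before 60 months are nonsurvivors; patients censored
#' before 60 months carry no 5-year information and are excluded (`NA`).
#'
#' @param times Follow-up times in months.
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @param horizon Classification horizon in months (default 60).
#' @return Factor with levels `nonsurvivor`, `survivor`; `NA` = excluded.
#' @export
#' @examples
#' five_year_label(c(61, 59, 30), c(1, 1, 0))  # survivor, nonsurvivor, NA
five_year_label <- function(times, events, horizon = 60) {
  lab <- ifelse(times >= horizon, "survivor",
                ifelse(events == 1, "nonsurvivor", NA))
  factor(lab, levels = c("nonsurvivor", "survivor"))
}

#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' The curve sweeps all distinct score values as thresholds under the rule
#' "score >= threshold => predicted positive". The AUC is computed both by
#' the trapezoid rule over the empirical curve and as the Mann-Whitney
#' probability with half credit for ties; the two agree identically.
#'
#' @param scores Numeric biomarker values.
#' @param labels Logical (or 0/1) class labels, `TRUE` = positive; the
#'   positive class is the one higher scores should predict.
#' @return Object of class `roc_curve`: `thresholds` (descending),
#'   `sensitivity`, `specificity`, `tp`, `fp`, `fpr`, `tpr` (curve vertices
#'   including the (0,0) anchor), `n_pos`, `n_neg`, `auc`, `auc_mw`,
#'   `auc_ci_95`, `orientation`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("undefined-ROC error: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  sc <- scores[o]; lb <- labels[o]
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)  # last index of each value
  thr <- sc[last]
  tp <- cumsum(lb)[last]
  fp <- cumsum(!lb)[last]
  sens <- tp / n1
  spec <- (n0 - fp) / n0
  fpr <- c(0, fp / n0)
  tpr <- c(0, tp / n1)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  rk <- rank(scores)
  auc_mw <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong structural components
  x <- scores[labels]; y <- scores[!labels]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  var_auc <- (if (n1 > 1L) stats::var(v10) / n1 else 0) +
             (if (n0 > 1L) stats::var(v01) / n0 else 0)
  half <- stats::qnorm(0.975) * sqrt(var_auc)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 tp = tp, fp = fp, fpr = fpr, tpr = tpr,
                 n_pos = n1, n_neg = n0, auc = auc, auc_mw = auc_mw,
                 auc_ci_95 = c(max(0, auc - half), min(1, auc + half)),
                 orientation = "higher scores predict the positive class"),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (95%% CI %.4f-%.4f), %d pos / %d neg\n",
              x$auc, x$auc_ci_95[1L], x$auc_ci_95[2L], x$n_pos, x$n_neg))
  invisible(x)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Youden-index optimal cutoff
#'
#' Maximizes `J = sensitivity + specificity - 1` over the observed
#' thresholds of a ROC curve. Ties are broken by higher specificity, then by
#' lower cutoff. The cutoff is always an observed biomarker value, applied
#' with the rule "value >= cutoff => predicted positive". Sensitivity and
#' specificity at the cutoff carry Wilson-score 95% CIs.
#'
#' @param roc A [roc_curve()].
#' @return Object of class `cutoff_result`: `cutoff`, `youden_j`,
#'   `sensitivity`, `specificity`, `sens_ci_95`, `spec_ci_95`, `rule`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sensitivity + roc$specificity - 1
  i <- order(-j, -roc$specificity, roc$thresholds)[1L]
  tp <- roc$tp[i]; fp <- roc$fp[i]
  structure(list(cutoff = roc$thresholds[i], youden_j = j[i],
                 sensitivity = roc$sensitivity[i],
                 specificity = roc$specificity[i],
                 sens_ci_95 = wilson_ci(tp, roc$n_pos),
                 spec_ci_95 = wilson_ci(roc$n_neg - fp, roc$n_neg),
                 rule = ">= cutoff is predicted positive"),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(paste0("<cutoff_result> cutoff = %.6g (J = %.4f), sens = %.3f",
                     " (%.3f-%.3f), spec = %.3f (%.3f-%.3f)\n"),
              x$cutoff, x$youden_j, x$sensitivity, x$sens_ci_95[1L],
              x$sens_ci_95[2L], x$specificity, x$spec_ci_95[1L],
              x$spec_ci_95[2L]))
  invisible(x)
}

.km_one <- function(times, events) {
  if (any(times <= 0)) stop("input error: times must be positive")
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(x) sum(times >= x), integer(1L))
  n_event <- vapply(ut, function(x) sum(times == x & events == 1), integer(1L))
  n_censor <- vapply(ut, function(x) sum(times == x & events == 0), integer(1L))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times <= t of (1 - d_i / n_i)`; censored subjects
#' leave the risk set after their censoring time. Without censoring this is
#' exactly `1 - ECDF` of the event times.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Optional group labels; when given, one curve per group.
#' @return A `km_curve` data frame (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`), or a named list of them when `groups` is given.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (is.null(groups)) return(.km_one(times, events))
  groups <- as.factor(as.character(groups))
  out <- lapply(levels(groups), function(g)
    .km_one(times[groups == g], events[groups == g]))
  names(out) <- levels(groups)
  out
}

#' Log-rank (Mantel-Cox) test for two groups
#'
#' At each distinct event time the observed events in group 1 are compared
#' with their hypergeometric expectation given the risk sets;
#' `chi^2 = (sum(O1 - E1))^2 / sum(V)` on 1 df.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param group Two-level group labels.
#' @return Object of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` (per group).
#' @export
log_rank <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L)
    stop("input error: log-rank requires exactly two groups")
  if (any(tabulate(group) == 0L)) stop("input error: empty group")
  if (sum(events) < 1L) stop("input error: no events")
  if (any(times <= 0)) stop("input error: times must be positive")
  g1 <- group == levels(group)[1L]
  ut <- sort(unique(times[events == 1]))
  n <- vapply(ut, function(x) sum(times >= x), integer(1L))
  n1 <- vapply(ut, function(x) sum(times >= x & g1), integer(1L))
  d <- vapply(ut, function(x) sum(times == x & events == 1), integer(1L))
  d1 <- vapply(ut, function(x) sum(times == x & events == 1 & g1), integer(1L))
  e1 <- d * n1 / n
  v <- ifelse(n > 1L, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  stat <- if (sum(v) == 0) 0 else sum(d1 - e1)^2 / sum(v)
  structure(list(chi_square = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 observed = c(sum(d1), sum(d) - sum(d1)),
                 expected = c(sum(e1), sum(d) - sum(e1)),
                 groups = levels(group)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4f (df = 1), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

# Efron partial likelihood, gradient and information for a single covariate.
# times ascending; risk set at an event time = all subjects with t >= it.
.cox_lik <- function(beta, t, d, x) {
  w <- exp(x * beta)
  s0 <- rev(cumsum(rev(w)))
  s1 <- rev(cumsum(rev(x * w)))
  s2 <- rev(cumsum(rev(x^2 * w)))
  ut <- unique(t)
  first <- match(ut, t)
  ll <- 0; U <- 0; I <- 0
  for (k in seq_along(ut)) {
    dd <- which(t == ut[k] & d == 1L)
    dk <- length(dd)
    if (dk == 0L) next
    sd0 <- sum(w[dd]); sd1 <- sum(x[dd] * w[dd]); sd2 <- sum(x[dd]^2 * w[dd])
    ll <- ll + sum(x[dd]) * beta
    U <- U + sum(x[dd])
    for (l in seq_len(dk) - 1L) {
      f <- l / dk
      den <- s0[first[k]] - f * sd0
      a1 <- s1[first[k]] - f * sd1
      a2 <- s2[first[k]] - f * sd2
      ll <- ll - log(den)
      U <- U - a1 / den
      I <- I + a2 / den - (a1 / den)^2
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Univariate Cox proportional hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with Efron handling
#' of tied event times; convergence when the step falls below `tol` (default
#' 1e-8) within `max_iter` iterations. The standard error comes from the
#' observed information. Monotone likelihoods (perfect separation) are
#' flagged as non-converged and no estimate is reported.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param covariate Numeric covariate (must vary).
#' @param max_iter,tol Newton-Raphson controls.
#' @return Object of class `cox_result`: `beta`, `hazard_ratio`, `se`,
#'   `z`, `p_value`, `hr_ci_95`, `converged`, `n_iter`, `n_events`.
#' @export
cox_univariate <- function(times, events, covariate, max_iter = 50L,
                           tol = 1e-8) {
  if (any(times <= 0)) stop("input error: times must be positive")
  if (sum(events) < 1L) stop("input error: no events")
  if (stats::var(covariate) == 0)
    stop("input error: covariate does not vary")
  ord <- order(times)
  t <- times[ord]; d <- as.integer(events[ord]); x <- covariate[ord]
  beta <- 0; converged <- FALSE; it <- 0L
  cur <- .cox_lik(beta, t, d, x)
  while (it < max_iter) {
    it <- it + 1L
    if (cur$info <= 0) break
    step <- cur$score / cur$info
    new_beta <- beta + step
    nxt <- .cox_lik(new_beta, t, d, x)
    h <- 0L
    while (nxt$loglik < cur$loglik && h < 20L) {  # step halving guard
      h <- h + 1L
      step <- step / 2
      new_beta <- beta + step
      nxt <- .cox_lik(new_beta, t, d, x)
    }
    beta <- new_beta; cur <- nxt
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  if (abs(beta) > 20) converged <- FALSE  # monotone likelihood
  if (!converged) {
    return(structure(list(beta = NA_real_, hazard_ratio = NA_real_,
                          se = NA_real_, z = NA_real_, p_value = NA_real_,
                          hr_ci_95 = c(NA_real_, NA_real_),
                          converged = FALSE, n_iter = it,
                          n_events = sum(d)),
                     class = "cox_result"))
  }
  se <- 1 / sqrt(cur$info)
  z <- beta / se
  structure(list(beta = beta, hazard_ratio = exp(beta), se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 hr_ci_95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 converged = TRUE, n_iter = it, n_events = sum(d)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  if (!x$converged) {
    cat("<cox_result> did not converge (monotone likelihood?)\n")
  } else {
    cat(sprintf("<cox_result> HR = %.4f (95%% CI %.4f-%.4f), p = %.4g\n",
                x$hazard_ratio, x$hr_ci_95[1L], x$hr_ci_95[2L], x$p_value))
  }
  invisible(x)
}

#' Cox score test at beta = 0
#'
#' `U(0)^2 / I(0)`. For a binary covariate without tied event times this
#' equals the log-rank chi-square.
#'
#' @inheritParams cox_univariate
#' @return The score chi-square statistic (1 df).
#' @export
cox_score_test <- function(times, events, covariate) {
  ord <- order(times)
  lk <- .cox_lik(0, times[ord], as.integer(events[ord]), covariate[ord])
  lk$score^2 / lk$info
}

#' End-to-end biomarker evaluation of one gene in a cohort
#'
#' Runs the full clinical-endpoint pipeline: 5-year survivor labels (patients
#' censored before 60 months excluded from classification), empirical ROC and
#' AUC with DeLong CI, Youden cutoff with Wilson CIs, dichotomization of the
#' whole cohort at the cutoff, Kaplan-Meier curves, log-rank test, and a
#' univariate Cox model with covariate 1 = low expression (so the hazard
#' ratio is for low vs high expressors). The report is deterministic given
#' the input.
#'
#' @param cohort Data frame with columns `time_months`, `event` and the
#'   gene's expression (column `gene` or `<gene>_rpkm`).
#' @param gene Gene name, e.g. `"MDL1AS"`.
#' @return Object of class `biomarker_report`.
#' @export
biomarker_report <- function(cohort, gene) {
  col <- if (gene %in% names(cohort)) gene else paste0(gene, "_rpkm")
  if (!col %in% names(cohort))
    stop("input error: no expression column for gene '", gene, "'")
  expr <- cohort[[col]]
  lab <- five_year_label(cohort$time_months, cohort$event)
  keep <- !is.na(lab)
  roc <- roc_curve(expr[keep], lab[keep] == "survivor")
  cut <- youden_cutoff(roc)
  high <- expr >= cut$cutoff
  grp <- factor(ifelse(high, "high", "low"), levels = c("high", "low"))
  km <- km_estimate(cohort$time_months, cohort$event, grp)
  lr <- log_rank(cohort$time_months, cohort$event, grp)
  cox <- cox_univariate(cohort$time_months, cohort$event, as.numeric(!high))
  structure(list(gene = gene, n = nrow(cohort), n_excluded = sum(!keep),
                 n_survivor = sum(lab[keep] == "survivor"),
                 n_nonsurvivor = sum(lab[keep] == "nonsurvivor"),
                 roc = roc, cutoff = cut, km = km, log_rank = lr, cox = cox),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat(sprintf("== biomarker report: %s (n = %d, %d excluded) ==\n",
              x$gene, x$n, x$n_excluded))
  print(x$roc); print(x$cutoff); print(x$log_rank); print(x$cox)
  invisible(x)
}

#' Serialize a biomarker report to JSON
#'
#' @param report A [biomarker_report()].
#' @param path Output file, or `NULL` to return the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_biomarker_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "biomarker_report"))
  obj <- list(gene = report$gene, n = report$n,
              n_excluded = report$n_excluded,
              auc = report$roc$auc, auc_ci_95 = report$roc$auc_ci_95,
              cutoff = report$cutoff$cutoff,
              youden_j = report$cutoff$youden_j,
              sensitivity = report$cutoff$sensitivity,
              sens_ci_95 = report$cutoff$sens_ci_95,
              specificity = report$cutoff$specificity,
              spec_ci_95 = report$cutoff$spec_ci_95,
              log_rank_chi_square = report$log_rank$chi_square,
              log_rank_p = report$log_rank$p_value,
              cox_hr_low_vs_high = report$cox$hazard_ratio,
              cox_hr_ci_95 = report$cox$hr_ci_95,
              cox_p = report$cox$p_value)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
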