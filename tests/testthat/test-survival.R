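# Survival-biomarker engine: ROC/AUC, Youden cutoff, Kaplan-Meier, log-rank,
# Cox. The survival package serves as the independent oracle where one
# exists; elsewhere brute-force enumeration.

test_that("roc_curve: trapezoid AUC equals pair counting, ties included", {
  sep <- roc_curve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(sep$auc, 1)
  expect_equal(sep$auc_mw, 1)

  toy_s <- c(1, 2, 3, 3, 4, 5)
  toy_l <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  toy <- roc_curve(toy_s, toy_l)
  expect_equal(toy$auc, oracle_auc_pairs(toy_s, toy_l), tolerance = 1e-15)
  expect_equal(toy$auc, toy$auc_mw, tolerance = 1e-15)

  set.seed(51)
  null <- roc_curve(rnorm(2000), sample(c(TRUE, FALSE), 2000, TRUE))
  expect_lt(abs(null$auc - 0.5), 0.05)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "undefined-ROC")

  for (i in 1:50) {
    n <- sample(8:40, 1)
    s <- round(runif(n, 0, 4), 1)  # heavy ties
    l <- runif(n) < 0.5
    if (all(l) || !any(l)) l[1:2] <- c(TRUE, FALSE)
    r <- roc_curve(s, l)
    expect_equal(r$auc, r$auc_mw, tolerance = 1e-12)
    expect_equal(r$auc, oracle_auc_pairs(s, l), tolerance = 1e-12)
    # curve anchors and monotone sensitivity along descending thresholds
    expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[length(r$fpr)], 1)
    expect_equal(r$tpr[length(r$tpr)], 1)
    expect_true(all(diff(r$sensitivity) >= 0))
    expect_true(r$auc_ci_95[1] <= r$auc && r$auc <= r$auc_ci_95[2])
  }
})

test_that("youden_cutoff equals exhaustive threshold search", {
  toy <- youden_cutoff(roc_curve(c(1, 2, 3, 4, 5, 6),
                                 c(F, F, F, T, T, T)))
  expect_equal(toy$cutoff, 4)
  expect_equal(toy$youden_j, 1)
  expect_equal(toy$sensitivity, 1)
  expect_equal(toy$specificity, 1)
  set.seed(52)
  for (i in 1:30) {
    s <- round(runif(40, 0, 10), 1)
    l <- runif(40) < 0.4
    if (all(l) || !any(l)) l[1:2] <- c(TRUE, FALSE)
    got <- youden_cutoff(roc_curve(s, l))
    want <- oracle_youden(s, l)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$sens, tolerance = 1e-12)
    expect_equal(got$specificity, want$spec, tolerance = 1e-12)
  }
})

test_that("km_estimate is the product-limit estimator", {
  # no censoring: exactly 1 - ECDF at every observed time
  set.seed(53)
  t <- round(rexp(40, 0.1), 2) + 0.01
  km <- km_estimate(t, rep(1, 40))
  expect_equal(km$surv, 1 - stats::ecdf(t)(km$time), tolerance = 1e-12)

  expect_true(all(km_estimate(t, rep(0, 40))$surv == 1))

  # 10-subject mixed toy data against the survival package
  tt <- c(1, 2, 2, 3, 5, 6, 6, 8, 9, 12)
  ev <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  got <- km_estimate(tt, ev)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(got$surv[got$n_event > 0],
               summary(sf)$surv, tolerance = 1e-12)
  # the exact censoring time after the last event is irrelevant: moving the
  # subject censored at 12 out to 20 leaves S at every event time unchanged
  got2 <- km_estimate(c(tt[-10], 20), c(ev[-10], 0))
  expect_equal(got2$surv[got2$n_event > 0], got$surv[got$n_event > 0],
               tolerance = 1e-12)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "input error")
})

test_that("log_rank matches survdiff and is label-swap invariant", {
  t <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  g <- rep(c("a", "b"), each = 5)
  same <- log_rank(c(t[1:5], t[1:5]), rep(1, 10), g)
  expect_equal(same$chi_square, 0)

  set.seed(54)
  for (i in 1:10) {
    n <- 60
    tt <- round(rexp(n, 0.2), 1) + 0.1  # ties likely
    ev <- as.integer(runif(n) < 0.8)
    gg <- sample(c("x", "y"), n, TRUE)
    if (length(unique(gg)) < 2) gg[1:2] <- c("x", "y")
    got <- log_rank(tt, ev, gg)
    ref <- survival::survdiff(survival::Surv(tt, ev) ~ gg)
    expect_equal(got$chi_square, ref$chisq, tolerance = 1e-8)
    swap <- log_rank(tt, ev, ifelse(gg == "x", "y", "x"))
    expect_equal(got$chi_square, swap$chi_square, tolerance = 1e-12)
  }
  expect_error(log_rank(t, rep(0, 10), g), "no events")
})

test_that("cox_univariate matches coxph with Efron ties", {
  set.seed(55)
  for (i in 1:10) {
    n <- 80
    x <- rnorm(n)
    tt <- round(rexp(n, 0.1 * exp(0.5 * x)), 1) + 0.1
    ev <- as.integer(runif(n) < 0.85)
    if (sum(ev) == 0) ev[1] <- 1L
    got <- cox_univariate(tt, ev, x)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = "efron")
    expect_true(got$converged)
    expect_equal(got$beta, unname(stats::coef(ref)), tolerance = 1e-6)
    expect_equal(got$se, sqrt(unname(stats::vcov(ref)[1, 1])),
                 tolerance = 1e-6)
  }
})

test_that("cox score test at beta = 0 equals log-rank for binary covariates without ties", {
  set.seed(56)
  for (i in 1:10) {
    n <- 100
    x <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.05 * exp(0.7 * x))  # continuous: no ties
    ev <- as.integer(runif(n) < 0.9)
    if (sum(ev) == 0) ev[1] <- 1L
    sc <- cox_score_test(tt, ev, x)
    lr <- log_rank(tt, ev, x)$chi_square
    expect_lt(abs(sc - lr) / lr, 1e-6)
  }
})

test_that("cox flags monotone likelihoods and null covariates behave", {
  # perfect separation: covariate perfectly orders the event times
  tt <- 1:20
  got <- cox_univariate(tt, rep(1, 20), as.numeric(tt))
  expect_false(got$converged)
  expect_true(is.na(got$hazard_ratio))
  # independent covariate at large n: beta near 0
  set.seed(57)
  n <- 1500
  x <- rnorm(n)
  t2 <- rexp(n, 0.1)
  got2 <- cox_univariate(t2, rep(1, n), x)
  expect_lt(abs(got2$beta), 3 * got2$se)
  expect_error(cox_univariate(t2, rep(1, n), rep(2, n)), "vary")
})

test_that("cox Wald CI coverage of a true HR of 2 is calibrated", {
  set.seed(58)
  hit <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    n <- 500
    x <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.05 * exp(log(2) * x))
    cens <- stats::runif(n, 0, 40)
    ev <- as.integer(tt <= cens)
    time <- pmin(tt, cens)
    fit <- cox_univariate(time, ev, x)
    if (fit$converged && fit$hr_ci_95[1] <= 2 && 2 <= fit$hr_ci_95[2])
      hit <- hit + 1L
  }
  # two-sided binomial band around the nominal 95% coverage
  expect_lt(abs(hit / reps - 0.95), 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("five_year_label implements the >= 60-month rule with exclusion", {
  lab <- five_year_label(c(61, 59, 30, 60, 200), c(1, 1, 0, 0, 0))
  expect_identical(as.character(lab),
                   c("survivor", "nonsurvivor", NA, "survivor", "survivor"))
})

test_that("biomarker_report is deterministic and recovers strong separation", {
  set.seed(59)
  n <- 120
  expr <- c(runif(n / 2, 500, 1979), runif(n / 2, 1981, 4000))
  time <- ifelse(expr >= 1980, runif(n, 80, 150), runif(n, 2, 50))
  cohort <- data.frame(MDL1AS_rpkm = expr, time_months = time,
                       event = rep(1L, n))
  r1 <- biomarker_report(cohort, "MDL1AS")
  r2 <- biomarker_report(cohort, "MDL1AS")
  expect_identical(r1, r2)
  expect_equal(r1$roc$auc, 1)
  # cutoff is the smallest positive-class value under the >= rule
  expect_equal(r1$cutoff$cutoff, min(expr[expr >= 1980]))
  expect_equal(r1$cutoff$youden_j, 1)
  expect_lt(r1$log_rank$p_value, 1e-6)
  # every low-expressor event precedes every high-expressor event, so the
  # Cox partial likelihood is monotone and must be flagged, not reported
  expect_false(r1$cox$converged)
  js <- write_biomarker_json(r1)
  expect_true(jsonlite::validate(js))
  expect_error(biomarker_report(cohort, "NOPE"), "input error")
})
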