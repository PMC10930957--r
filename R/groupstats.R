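# Group-level statistics: one-way ANOVA with Sidak-adjusted pairwise
# comparisons, Welch tests, Pearson chi-square, and Benjamini-Hochberg FDR.
# Test statistics are computed from first principles; only the reference
# distributions (pf, pt, pchisq) come from stats.

test_result <- function(statistic, df, p_value, method,
                        adjusted_p = NA_real_, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p_value = p_value,
                   adjusted_p = adjusted_p, method = method), extra),
            class = "mito_test")
}

#' @export
print.mito_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test: between- over within-group mean squares,
#' p from `F(k - 1, N - k)`.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor), one per observation.
#' @return A `mito_test` with the F statistic and `df = c(df1, df2)`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  stopifnot(length(values) == length(groups))
  ns <- tabulate(groups)
  if (nlevels(groups) < 2L || any(ns < 2L))
    stop("input error: need >= 2 groups with >= 2 values each")
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (ssw == 0 && ssb == 0)
    stop("degenerate-input error: zero variance within and between groups")
  f <- (ssb / df1) / (ssw / df2)   # Inf when ssw == 0 but means differ
  test_result(f, c(df1, df2),
              stats::pf(f, df1, df2, lower.tail = FALSE), "one-way ANOVA")
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to 1. Monotone in both `p` and `m`.
#'
#' @param p_values Vector of p values in `[0, 1]`.
#' @param m Number of comparisons (>= number of p values; default
#'   `length(p_values)`).
#' @return Adjusted p values.
#' @export
#' @examples
#' sidak_adjust(0.01, m = 3)  # 0.029701
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("input error: p values outside [0, 1]")
  pmin(1, 1 - (1 - p_values)^m)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `p_(i) * n / i` from the largest rank down, with a cumulative minimum so
#' the output is monotone, then clipped to 1.
#'
#' @param p_values Vector of p values in `[0, 1]`.
#' @return Adjusted p values in the original order; an empty input returns
#'   an empty vector.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p_values) {
  n <- length(p_values)
  if (n == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("input error: p values outside [0, 1]")
  ord <- order(p_values)
  adj <- p_values[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(1, adj)
  out
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided p.
#'
#' @param group_a,group_b Numeric samples with `n >= 2` each.
#' @return A `mito_test`.
#' @export
welch_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("input error: each group needs n >= 2")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0 && mean(group_a) == mean(group_b))
    stop("degenerate-input error: zero variance and equal means")
  se2 <- va / na + vb / nb
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  test_result(t, df, 2 * stats::pt(-abs(t), df), "Welch t")
}

#' Pearson chi-square test on a contingency table
#'
#' @param table Matrix of non-negative counts (e.g. 2x2).
#' @param correct Apply the Yates continuity correction (2x2 only; default
#'   `FALSE`).
#' @param method `"chisq"` (default) or `"fisher"` (delegates to
#'   [stats::fisher.test()], 2x2 only).
#' @return A `mito_test`.
#' @export
chi_square <- function(table, correct = FALSE, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0)) stop("input error: negative counts")
  if (method == "fisher") {
    ft <- stats::fisher.test(table)
    return(test_result(NA_real_, NA_real_, ft$p.value, "Fisher exact"))
  }
  e <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(e == 0)) stop("degenerate-input error: empty row or column")
  d <- abs(table - e)
  if (correct && all(dim(table) == 2L)) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / e)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              if (correct) "Pearson chi-square (Yates)" else "Pearson chi-square")
}

#' Pairwise group comparisons after ANOVA
#'
#' Welch t tests for every pair of groups, Sidak-adjusted over the number of
#' pairs -- the usual follow-up to a one-way ANOVA.
#'
#' @inheritParams one_way_anova
#' @return Data frame with `contrast`, `statistic`, `p`, `p_adj`, `method`.
#' @export
pairwise_sidak <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  res <- apply(pairs, 2L, function(pr) {
    tt <- welch_t(values[groups == pr[1L]], values[groups == pr[2L]])
    data.frame(contrast = paste(pr, collapse = " vs "),
               statistic = tt$statistic, p = tt$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- sidak_adjust(out$p, m = ncol(pairs))
  out$method <- "Welch t + Sidak"
  out
}
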