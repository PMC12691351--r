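#' Univariate screening configuration
#'
#' @param alpha family significance level.
#' @param n_tests number of hypotheses (default 50, the MRMR selection size);
#'   the Bonferroni-adjusted threshold is `alpha / n_tests`.
#' @param normality_alpha Shapiro-Wilk threshold for test choice.
#' @return object of class `stats_config` with `adjusted_alpha` filled in.
#' @export
stats_config <- function(alpha = 0.05, n_tests = 50, normality_alpha = 0.05) {
  stopifnot(alpha > 0, n_tests >= 1)
  structure(list(alpha = alpha, n_tests = n_tests,
                 adjusted_alpha = alpha / n_tests,
                 normality_alpha = normality_alpha),
            class = "stats_config")
}

#' Choose the two-group test for one feature
#'
#' Welch's two-sample t-test when the Shapiro-Wilk test does not reject
#' normality (p > `normality_alpha`) in both groups; otherwise the two-sided
#' Mann-Whitney U test (normal approximation with tie correction). A
#' constant group, for which Shapiro-Wilk is undefined, routes to
#' Mann-Whitney.
#'
#' @param x0,x1 numeric samples of the two groups (>= 3 each).
#' @param normality_alpha Shapiro-Wilk threshold.
#' @return list `test` ("t" or "mann-whitney"), `p_value`.
#' @export
choose_test <- function(x0, x1, normality_alpha = 0.05) {
  stopifnot(length(x0) >= 3, length(x1) >= 3)
  sw <- function(x) {
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  normal <- sw(x0) > normality_alpha && sw(x1) > normality_alpha
  if (normal) {
    list(test = "t",
         p_value = stats::t.test(x0, x1, var.equal = FALSE)$p.value)
  } else {
    list(test = "mann-whitney",
         p_value = suppressWarnings(
           stats::wilcox.test(x0, x1, exact = FALSE,
                              correct = TRUE)$p.value))
  }
}

#' Univariate screen of selected features
#'
#' Per-feature two-group test chosen by [choose_test()], with pass flags at
#' the raw level and at the Bonferroni-adjusted threshold, plus group
#' medians and interquartile ranges.
#'
#' @param X feature matrix restricted to the screened (e.g. MRMR-selected)
#'   features.
#' @param y binary labels.
#' @param cfg `stats_config`.
#' @return data.frame sorted by p-value: feature, test, p_value, raw_pass,
#'   bonferroni_pass, median/IQR per group.
#' @export
screen_features <- function(X, y, cfg = stats_config()) {
  y <- as.integer(y)
  stopifnot(any(y == 0), any(y == 1))
  rows <- lapply(seq_len(ncol(X)), function(j) {
    x0 <- X[y == 0, j]; x1 <- X[y == 1, j]
    ct <- choose_test(x0, x1, cfg$normality_alpha)
    data.frame(feature = colnames(X)[j], test = ct$test,
               p_value = ct$p_value,
               raw_pass = ct$p_value < cfg$alpha,
               bonferroni_pass = ct$p_value < cfg$adjusted_alpha,
               median_low = stats::median(x0), iqr_low = stats::IQR(x0),
               median_high = stats::median(x1), iqr_high = stats::IQR(x1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), ]
}
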