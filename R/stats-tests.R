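#' Binomial excess test for neuron-selection counts
#'
#' Tests whether the number of neurons passing a selection procedure exceeds
#' what chance alone would produce, against a fixed per-neuron chance level
#' (5% by convention when the selection threshold is P < 0.05).
#'
#' @param k Number of selected neurons (0 <= k <= n).
#' @param n Total number of neurons screened.
#' @param p0 Chance probability of selecting a single neuron. Default 0.05.
#' @param strict If `TRUE` (default) the p-value is the strict upper tail
#'   P(X > k); if `FALSE`, P(X >= k). The strict tail is the convention this
#'   package standardizes on for published selection counts.
#' @return A `test_result` list with `statistic` (k), `p_value`, `n`,
#'   `estimate` (k/n) and `null_value` (p0).
#' @examples
#' binomial_excess_test(89, 874)$p_value   # ~1.6e-10
#' @export
binomial_excess_test <- function(k, n, p0 = 0.05, strict = TRUE) {
  stopifnot(length(k) == 1, length(n) == 1, is.finite(k), is.finite(n))
  if (k < 0 || n < 1 || k > n) stop("require 0 <= k <= n with n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  q <- if (strict) k else k - 1
  p <- stats::pbinom(q, n, p0, lower.tail = FALSE)
  test_result(statistic = k, p_value = p, n = n,
              estimate = k / n, null_value = p0,
              method = sprintf("binomial excess test (%s tail)",
                               if (strict) "strict" else "weak"))
}

#' Chi-square test comparing two selection proportions
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table
#' `[[k1, n1-k1], [k2, n2-k2]]`. Used to compare the proportion of, e.g.,
#' memorability-encoding neurons among feature neurons against the whole
#' recorded population; the two groups may overlap (subpopulation vs whole
#' population), matching how such enrichments are conventionally reported.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return A `test_result` with `statistic` (X-squared), `p_value`, `df`.
#' @examples
#' chi2_proportions(25, 89, 77, 874)$p_value  # ~1.79e-8
#' @export
chi2_proportions <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("require 0 <= k <= n")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("chi-square undefined: an expected cell is 0")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(statistic = unname(res$statistic), p_value = res$p.value,
              df = 1, n = n1 + n2, method = "Pearson chi-square, 2x2, df = 1")
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' @param p Vector of p-values.
#' @param q FDR level (default 0.05).
#' @return Logical vector, `TRUE` where the hypothesis is rejected at level q.
#' @export
bh_fdr <- function(p, q = 0.05) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH") <= q
}

#' Paired or two-sample t-test with effect size
#'
#' Thin wrapper around [stats::t.test()] returning the t statistic, df,
#' p-value, Cohen's d (paired: mean difference over SD of differences;
#' two-sample: pooled-SD standardized mean difference) and the CI of the mean
#' difference. Degenerate zero-variance inputs return `NA` statistics rather
#' than an error.
#'
#' @param a,b Numeric samples; equal length and pairwise when `paired = TRUE`.
#' @param paired Paired test? Default `TRUE`.
#' @param alternative Passed to [stats::t.test()].
#' @return A `test_result` with `statistic`, `df`, `p_value`, `effect_size`,
#'   `conf_int`, `n`.
#' @export
paired_samples_test <- function(a, b, paired = TRUE,
                                alternative = "two.sided") {
  keep <- if (paired) stats::complete.cases(a, b) else TRUE
  if (paired) { a <- a[keep]; b <- b[keep] }
  n <- if (paired) length(a) else c(length(a), length(b))
  degenerate <- if (paired) {
    length(a) < 2 || stats::sd(a - b) == 0
  } else {
    length(a) < 2 || length(b) < 2 || (stats::sd(a) == 0 && stats::sd(b) == 0)
  }
  if (degenerate) {
    return(test_result(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                       effect_size = NA_real_, conf_int = c(NA_real_, NA_real_),
                       n = n, method = "t-test (degenerate: zero variance)"))
  }
  res <- stats::t.test(a, b, paired = paired, alternative = alternative)
  d <- if (paired) {
    mean(a - b) / stats::sd(a - b)
  } else {
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }
  test_result(statistic = unname(res$statistic), p_value = res$p.value,
              df = unname(res$parameter), effect_size = d,
              conf_int = as.numeric(res$conf.int), n = n,
              method = res$method)
}

test_result <- function(...) {
  structure(list(...), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method %||% "test", "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 3), "\n")
  if (!is.null(x$effect_size) && !is.na(x$effect_size))
    cat("  effect size d =", format(x$effect_size, digits = 3), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
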