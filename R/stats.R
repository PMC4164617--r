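## Univariate statistics of the response analysis. The heavy lifting is done
## by the stats package; these wrappers pin the conventions used throughout
## the pipeline: two-sided tests, exact small-sample distributions for
## tie-free data up to n = 25 (so 12-vs-11 group comparisons are exact),
## and normal approximation with tie/continuity correction beyond that.

test_result <- function(statistic, p_value, method, exact) {
  structure(list(statistic = unname(statistic),
                 p_value = min(max(unname(p_value), 0), 1),
                 method = method, exact = exact),
            class = "dwi_test")
}

#' @export
print.dwi_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%s)\n", x$method,
              x$statistic, x$p_value, if (x$exact) "exact" else "approximate"))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `x - y`. Zero differences are
#' dropped (classic Wilcoxon convention); ties among the remaining absolute
#' differences get mid-ranks. The exact distribution is used when at most 25
#' non-zero differences remain and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `method` and `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_validation("x and y must be paired vectors of equal length >= 2")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; test is degenerate")
    return(test_result(0, 1, "Wilcoxon signed-rank", exact = TRUE))
  }
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result(ht$statistic, ht$p.value, "Wilcoxon signed-rank", exact)
}

#' Mann-Whitney U test
#'
#' Two-sided unpaired rank-sum comparison of two groups. Exact enumeration
#' is used when the pooled sample size is at most 25 and the pooled data are
#' tie-free; otherwise the normal approximation with tie and continuity
#' correction. The reported statistic is `U = min(U_x, U_y)`.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A list with `statistic` (U), `p_value`, `method` and `exact`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop_validation("both groups must be non-empty")
  exact <- (length(x) + length(y)) <= 25 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  ux <- unname(ht$statistic)                 # wilcox.test reports U_x
  test_result(min(ux, length(x) * length(y) - ux), ht$p.value,
              "Mann-Whitney U", exact)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A list with `statistic` (r), `p_value` (two-sided, from the
#'   t-distribution with n - 2 degrees of freedom), `method` and `exact`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_validation("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_degenerate("zero variance in input")
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result(ht$estimate, ht$p.value, "Pearson correlation", exact = FALSE)
}
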