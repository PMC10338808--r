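# Cohort-table statistics: unadjusted group regressions and background
# comparison tests.

#' Unadjusted group regression of an outcome score
#'
#' Ordinary least squares of a per-subject score on the group indicator
#' (optimal = 1, nonoptimal = 0).  The coefficient beta equals the
#' difference of group means exactly; its 95% confidence interval comes
#' from the t distribution with n - 2 degrees of freedom, and residual
#' normality is screened with the Shapiro-Wilk test.
#'
#' @param scores numeric per-subject outcome (IQ scale mean 100 SD 15, or
#'   a standard-score scale mean 10 SD 3).
#' @param groups per-subject labels; values \code{"optimal"} /
#'   \code{"nonoptimal"} (or a logical/0-1 indicator of the optimal
#'   group).
#' @param level confidence level (default 0.95).
#' @return a list of class \code{"RegressionResult"}: \code{beta},
#'   \code{ci} (lower/upper), \code{p_value},
#'   \code{residual_normality_p}, \code{n}.
#' @examples
#' sc <- c(rnorm(10, 10.8, 2.1), rnorm(10, 8.2, 2.3))
#' gr <- rep(c("optimal", "nonoptimal"), each = 10)
#' olsGroupBeta(sc, gr)
#' @export
olsGroupBeta <- function(scores, groups, level = 0.95) {
  ind <- if (is.logical(groups) || is.numeric(groups)) {
    as.numeric(groups)
  } else {
    as.numeric(as.character(groups) == "optimal")
  }
  if (length(unique(ind)) < 2L) stop("both groups must be present")
  if (length(scores) < 3L) stop("need at least 3 subjects")
  fit <- stats::lm(scores ~ ind)
  sm <- summary(fit)
  ci <- stats::confint(fit, "ind", level = level)
  swp <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                  error = function(e) NA_real_)
  structure(list(beta = unname(stats::coef(fit)["ind"]),
                 ci = c(lower = ci[1L], upper = ci[2L]),
                 p_value = sm$coefficients["ind", "Pr(>|t|)"],
                 residual_normality_p = swp,
                 n = length(scores)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("beta = %.3f (CI %.3f to %.3f), p = %.4g, n = %d\n",
              x$beta, x$ci[1L], x$ci[2L], x$p_value, x$n))
  invisible(x)
}

#' Fisher's exact test for a 2 x k contingency table
#'
#' Exact two-sided p-value by enumeration over tables with fixed margins
#' (network algorithm for larger tables).
#'
#' @param table matrix of counts (2 rows, k columns), all margins > 0.
#' @return the exact p-value.
#' @export
fisherExact <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin in contingency table")
  stats::fisher.test(table)$p.value
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two continuous samples with the
#' tie-corrected normal approximation.
#'
#' @param x,y numeric samples.
#' @return a list: \code{U} (statistic for \code{x} over \code{y}) and
#'   \code{p}.
#' @export
mannWhitneyU <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Kendall's tau-b with tie correction
#'
#' @param x,y paired numeric (or ordered categorical, coerced to rank)
#'   vectors.
#' @return a list: \code{tau} (tau-b) and \code{p} (two-sided, normal
#'   approximation under ties).
#' @export
kendallTauB <- function(x, y) {
  ht <- suppressWarnings(stats::cor.test(as.numeric(x), as.numeric(y),
                                         method = "kendall",
                                         exact = FALSE))
  list(tau = unname(ht$estimate), p = ht$p.value)
}
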