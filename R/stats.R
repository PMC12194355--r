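# Paired statistical comparisons used by the per-dose summaries.

#' Two-sided paired t-test
#'
#' Textbook paired t-test on the differences `a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))`. Zero-variance differences (all equal)
#' yield a not-computable marker (`NA` statistic and p-value with a note),
#' not an error.
#'
#' @param a,b paired numeric samples of equal length `n >= 2`.
#' @return a `"stat_result"` list: `test`, `statistic`, `p_value`, `n`,
#'   `df`, `mean_difference`, `note`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) {
    return(structure(list(test = "paired t-test", statistic = NA_real_,
                          p_value = NA_real_, n = n, df = n - 1,
                          mean_difference = mean(d),
                          note = "zero-variance differences"),
                     class = "stat_result"))
  }
  # textbook statistic, robust to near-constant differences
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  structure(list(test = "paired t-test",
                 statistic = t_stat,
                 p_value = 2 * pt(abs(t_stat), df = n - 1,
                                  lower.tail = FALSE),
                 n = n, df = n - 1,
                 mean_difference = mean(d), note = NULL),
            class = "stat_result")
}

#' TOST equivalence test for paired samples
#'
#' Two one-sided paired t-tests of the mean difference against the
#' equivalence bounds `-delta` and `+delta` (default `delta = 1`, e.g. one
#' point on a five-point Likert scale). The overall p-value is the maximum
#' of the two one-sided p-values; equivalence is concluded at `p < 0.05`.
#'
#' @param a,b paired numeric samples of equal length `n >= 2`.
#' @param delta positive equivalence half-width.
#' @return a `"stat_result"` list with the two one-sided p-values
#'   (`p_lower`, `p_upper`), overall `p_value = max(p_lower, p_upper)`,
#'   `bounds`, `n` and `mean_difference`.
#' @export
tost_equivalence <- function(a, b, delta = 1.0) {
  if (delta <= 0) stop("delta must be positive")
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  if (sd(d) == 0) {
    return(structure(list(test = "TOST equivalence", statistic = NA_real_,
                          p_value = NA_real_, p_lower = NA_real_,
                          p_upper = NA_real_, bounds = c(-delta, delta),
                          n = n, mean_difference = mean(d),
                          note = "zero-variance differences"),
                     class = "stat_result"))
  }
  se <- sd(d) / sqrt(n)
  p_lower <- pt((mean(d) + delta) / se, df = n - 1, lower.tail = FALSE)
  p_upper <- pt((mean(d) - delta) / se, df = n - 1, lower.tail = TRUE)
  structure(list(test = "TOST equivalence",
                 statistic = NA_real_,
                 p_value = max(p_lower, p_upper),
                 p_lower = p_lower, p_upper = p_upper,
                 bounds = c(-delta, delta), n = n,
                 mean_difference = mean(d), note = NULL),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, "\n")
  cat(sprintf("  n = %d, mean difference = %.6g\n", x$n, x$mean_difference))
  if (!is.null(x$note)) {
    cat("  not computable:", x$note, "\n")
  } else if (identical(x$test, "TOST equivalence")) {
    cat(sprintf("  bounds = [%g, %g], p_lower = %.3g, p_upper = %.3g, p = %.3g\n",
                x$bounds[1], x$bounds[2], x$p_lower, x$p_upper, x$p_value))
  } else {
    cat(sprintf("  t = %.4g, df = %g, p = %.3g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}
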