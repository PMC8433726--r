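#' Two-tailed Student's t-test (pooled variance)
#'
#' Hand-coded equal-variance two-sample t: pooled variance
#' `sp2 = ((na-1) var(a) + (nb-1) var(b)) / (na + nb - 2)`, statistic
#' `t = (mean(a) - mean(b)) / sqrt(sp2 (1/na + 1/nb))`, `df = na + nb - 2`,
#' two-tailed p from the t distribution. Degenerate inputs with zero pooled
#' variance follow the convention t = 0, p = 1 when the means are equal and
#' p = 0 (flagged) when they differ. A Welch (unequal-variance) variant is
#' available behind `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors of readings, each of length >= 2.
#' @param alpha Significance level for the `significant` flag.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return A one-row tibble of class `ttest_result`: `estimate` (mean
#'   difference a - b), `statistic`, `df`, `p_value`, `significant`, `alpha`,
#'   `method`, `degenerate`.
#' @examples
#' student_t_two_tailed(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t_two_tailed <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    stop_voltphen("each group needs at least 2 readings.")
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    stop_voltphen("readings must be finite.")
  }
  check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  na <- length(a)
  nb <- length(b)
  ma <- mean(a)
  mb <- mean(b)
  va <- var(a)
  vb <- var(b)
  degenerate <- FALSE

  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    method <- "Student (pooled variance), two-tailed"
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- if (se > 0) {
      (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    } else {
      na + nb - 2
    }
    method <- "Welch, two-tailed"
  }

  if (se == 0) {
    degenerate <- TRUE
    if (ma == mb) {
      stat <- 0
      p <- 1
    } else {
      stat <- sign(ma - mb) * Inf
      p <- 0
      warn("zero pooled variance with unequal means: p set to 0 by convention.")
    }
  } else {
    stat <- (ma - mb) / se
    p <- 2 * pt(-abs(stat), df = df)
  }

  out <- tibble(
    estimate = ma - mb,
    statistic = stat,
    df = df,
    p_value = p,
    significant = p < alpha,
    alpha = alpha,
    method = method,
    degenerate = degenerate
  )
  class(out) <- c("ttest_result", class(tibble()))
  out
}
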