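#' Paired Z-test comparing two treatment rules
#'
#' Tests whether two estimated rules have the same value, using the difference
#' of their jackknife values over the *same* subjects divided by the standard
#' error of the paired influence residual differences:
#' `T = (V1 - V2) / sqrt(sum((R1_i - R2_i)^2) / (m (m - 1)))`,
#' with a two-sided standard normal p-value. Both estimates must be computed
#' on the same subject subset so the residuals pair by subject. Comparing a
#' rule with itself (identical residuals and values) is uninformative, not
#' erroneous: the statistic is 0 with p-value 1.
#'
#' @param est1,est2 `jackknife_estimate` objects sharing one subject subset.
#' @return An object of class `survjack_ztest` with `statistic`, `p_value`,
#'   `value_1`, `value_2`, `se_diff`, `m`, and the learner labels.
#' @export
z_test <- function(est1, est2) {
  stopifnot(inherits(est1, "jackknife_estimate"),
            inherits(est2, "jackknife_estimate"))
  if (est1$m != est2$m ||
      !identical(est1$components$id, est2$components$id)) {
    stop("The two estimates must be computed on the same subject subset ",
         "(pair the residuals by running both learners on one subset draw).",
         call. = FALSE)
  }
  m <- est1$m
  rdiff <- est1$components$residual - est2$components$residual
  se_diff <- sqrt(sum(rdiff^2) / (m * (m - 1)))
  num <- est1$value - est2$value
  if (se_diff == 0) {
    statistic <- if (num == 0) 0 else sign(num) * Inf
  } else {
    statistic <- num / se_diff
  }
  p_value <- 2 * pnorm(-abs(statistic))
  structure(
    list(statistic = statistic, p_value = p_value,
         value_1 = est1$value, value_2 = est2$value, se_diff = se_diff,
         m = m, learners = c(est1$learner, est2$learner)),
    class = "survjack_ztest")
}

#' @export
print.survjack_ztest <- function(x, ...) {
  cat("Z-test comparing treatment rules: ", x$learners[1], " vs ",
      x$learners[2], "\n", sep = "")
  cat("  values:", format(x$value_1, digits = 5), "vs",
      format(x$value_2, digits = 5), "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      " p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @rdname z_test
#' @param x A `survjack_ztest`.
#' @param ... Unused.
#' @export
tidy.survjack_ztest <- function(x, ...) {
  tibble::tibble(learner_1 = x$learners[1], learner_2 = x$learners[2],
                 value_1 = x$value_1, value_2 = x$value_2,
                 statistic = x$statistic, p_value = x$p_value,
                 se_diff = x$se_diff, m = x$m)
}

#' @rdname z_test
#' @export
glance.survjack_ztest <- function(x, ...) tidy(x)

#' Empirical power (or size) from a set of p-values
#'
#' The proportion of simulation p-values below the significance level,
#' together with its binomial Monte Carlo standard error
#' `sqrt(p_hat (1 - p_hat) / B)`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param level Significance level (default 0.05).
#' @return A one-row tibble with `power`, `mc_se`, `n_sim`, `level`.
#' @export
power_from_pvalues <- function(pvalues, level = 0.05) {
  if (!length(pvalues)) stop("`pvalues` must be nonempty.", call. = FALSE)
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  b <- length(pvalues)
  p_hat <- mean(pvalues < level)
  tibble::tibble(power = p_hat, mc_se = sqrt(p_hat * (1 - p_hat) / b),
                 n_sim = b, level = level)
}
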