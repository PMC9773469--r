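#' Q-Q plot of jackknife test statistics against N(0, 1)
#'
#' @param object A `survjack_qq` object from [qq_data()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survjack_qq <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$theoretical, y = .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Standard normal quantiles", y = "Empirical quantiles",
      title = "Jackknife test statistic vs N(0, 1)",
      subtitle = paste0("KS distance = ", signif(object$ks_distance, 3),
                        " (n = ", object$n, ")")) +
    ggplot2::theme_minimal()
}

#' Boxplots of value estimates across replicates
#'
#' Reproduces the value-distribution display of a simulation grid: one box of
#' jackknife value estimates per learner, faceted by sample size and censoring
#' rate.
#'
#' @param grid A `survjack_grid` from [run_power_grid()], or its `estimates`
#'   tibble.
#' @return A ggplot.
#' @export
plot_value_distribution <- function(grid) {
  est <- if (inherits(grid, "survjack_grid")) grid$estimates else grid
  ggplot2::ggplot(est, ggplot2::aes(x = .data$learner, y = .data$value,
                                    fill = .data$learner)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_grid(censoring ~ n,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Jackknife value estimate") +
    ggplot2::theme_minimal()
}

#' Power curves across sample sizes and censoring rates
#'
#' @param grid A `survjack_grid` from [run_power_grid()], or its `summary`
#'   tibble.
#' @return A ggplot.
#' @export
plot_power_curves <- function(grid) {
  s <- if (inherits(grid, "survjack_grid")) grid$summary else grid
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n, y = .data$power,
                                  colour = factor(.data$censoring),
                                  group = factor(.data$censoring))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(scenario ~ pair, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Sample size", y = "Power at the 5% level",
                  colour = "Censoring") +
    ggplot2::theme_minimal()
}
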