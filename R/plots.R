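#' Plot fitted prize-response curves
#'
#' Sigmoid curves of the conditional go-probability against prize size, one
#' panel per indication and one curve per prize phase, evaluated from the
#' baseline logistic fits over the sampled prize range.
#'
#' @param baseline An [run_baseline()] result.
#' @param prize_range Prize range in million USD to evaluate (log-spaced).
#' @return A ggplot object.
#' @export
plot_pgo_curves <- function(baseline, prize_range = c(0.1, 1e5)) {
  fits <- baseline$fits[baseline$fits$model == "pgo_logistic", ]
  z <- 10^seq(log10(prize_range[1]), log10(prize_range[2]), length.out = 200)
  curves <- fits %>%
    dplyr::rowwise() %>%
    dplyr::reframe(prize_size = z, pgo = plogis(beta0 + beta1 * log10(z)),
                   indication = indication, prize_phase = prize_phase)
  ggplot2::ggplot(curves,
                  ggplot2::aes(prize_size, pgo, colour = prize_phase)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~indication) +
    ggplot2::labs(x = "prize size (million USD)",
                  y = "P(go | no-decision)", colour = "prize phase") +
    ggplot2::theme_minimal()
}

#' Heatmap of mean cost savings over the target/inefficiency grid
#'
#' Mean per-market-approval cost savings of direct funding for one
#' indication, one panel per prize phase, with the zero-savings contour
#' separating regions where direct (positive) or indirect (negative)
#' funding is cheaper.
#'
#' @param grid An [run_grid()] result.
#' @param indication Indication to plot (default: first present).
#' @return A ggplot object.
#' @export
plot_savings_heatmap <- function(grid, indication = NULL) {
  if (is.null(indication)) indication <- grid$indication[1]
  g <- grid[grid$indication == indication, ]
  ggplot2::ggplot(g, ggplot2::aes(inefficiency, target_pgo,
                                  fill = mean_cost_savings)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::facet_wrap(~prize_phase) +
    ggplot2::labs(title = indication, x = "direct-funding inefficiency",
                  y = "target P(go)",
                  fill = "mean savings\n(MUSD/approval)") +
    ggplot2::theme_minimal()
}

#' Plot fitted zero-savings frontiers
#'
#' Quadratic frontier curves (maximum target go-probability before direct
#' funding is equally expensive) against inefficiency, one curve per
#' indication, one panel per prize phase.
#'
#' @param frontier An [fit_frontier()] result.
#' @return A ggplot object.
#' @export
plot_frontier <- function(frontier) {
  f <- frontier[!frontier$flagged, ]
  xs <- seq(0, 1, length.out = 101)
  curves <- f %>%
    dplyr::rowwise() %>%
    dplyr::reframe(inefficiency = xs, pgo = a + b * xs + c * xs^2,
                   indication = indication, prize_phase = prize_phase)
  ggplot2::ggplot(curves,
                  ggplot2::aes(inefficiency, pgo, colour = indication)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~prize_phase) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "direct-funding inefficiency",
                  y = "frontier P(go)") +
    ggplot2::theme_minimal()
}

#' Plot per-approval funding cost distributions
#'
#' Boxplots of the per-market-approval cost of indirect funding (the prize)
#' and direct funding (at the scenario inefficiency) across retained
#' projects, per prize phase and indication.
#'
#' @param scenario An [run_scenario()] result.
#' @param outliers Show boxplot outliers (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_cost_distributions <- function(scenario, outliers = FALSE) {
  long <- tidyr::pivot_longer(
    scenario$samples,
    c("direct_per_approval", "indirect_per_approval"),
    names_to = "perspective", values_to = "cost_per_approval"
  ) %>%
    mutate(perspective = ifelse(perspective == "direct_per_approval",
                                "direct", "indirect"))
  ggplot2::ggplot(long, ggplot2::aes(prize_phase, cost_per_approval,
                                     fill = perspective)) +
    ggplot2::geom_boxplot(outliers = outliers) +
    ggplot2::facet_wrap(~indication, scales = "free_y") +
    ggplot2::labs(x = "prize phase",
                  y = "cost per market approval (million USD)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.abx_baseline <- function(object, ...) plot_pgo_curves(object, ...)

#' @export
autoplot.abx_grid <- function(object, ...) plot_savings_heatmap(object, ...)

#' @export
autoplot.abx_frontier <- function(object, ...) plot_frontier(object)

#' @export
autoplot.abx_scenario <- function(object, ...) {
  plot_cost_distributions(object, ...)
}
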