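# Utilitarian plots: cost-effectiveness plane scatter and acceptability curve.

#' Plot the cost-effectiveness plane
#'
#' Scatter of the bootstrapped incremental (effect, cost) draws with the
#' point estimate marked.
#'
#' @param cloud An `icer_cloud`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(cloud) {
  df <- as.data.frame(cloud)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_effect,
                                   y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::annotate("point", x = attr(cloud, "delta_effect_hat"),
                      y = attr(cloud, "delta_cost_hat"),
                      colour = "red", size = 2) +
    ggplot2::labs(x = paste0("Incremental effect (",
                             attr(cloud, "effect_kind"), ")"),
                  y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve`.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  df <- as.data.frame(curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (EUR per effect unit)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
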