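# ggplot2 helpers for the three result shapes: signal bubbles, the sex
# volcano, and Kaplan-Meier cumulative incidence. These are thin layers
# over the plot-ready coordinate tables the analysis functions emit.

#' Bubble plot of ranked signal strength
#'
#' @param ranked A [rank_signals()] tibble.
#' @return A ggplot object: PT rank on x, drug on y facets implicit via
#'   colour; bubble size is the report count, fill the ROR.
#' @export
plot_signal_bubbles <- function(ranked) {
  coords <- bubble_coords(ranked)
  ggplot2::ggplot(coords,
                  ggplot2::aes(x = .data$rank,
                               y = stats::reorder(.data$pt, -.data$rank),
                               size = .data$n, colour = .data$ror)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~drug, scales = "free_y") +
    ggplot2::scale_colour_viridis_c(option = "plasma") +
    ggplot2::labs(x = "signal rank", y = NULL, size = "reports",
                  colour = "ROR") +
    ggplot2::theme_minimal()
}

#' Volcano plot of sex-stratified disproportionality
#'
#' @param volcano A [volcano_table()] tibble.
#' @param alpha Significance level drawn as the horizontal guide.
#' @return A ggplot object with `log2(ROR)` on x and `-log10(p)` on y;
#'   points right of zero are male-dominant, left female-dominant.
#' @export
plot_volcano <- function(volcano, alpha = 0.05) {
  ggplot2::ggplot(volcano,
                  ggplot2::aes(x = .data$log2_ror, y = .data$neg_log10_p,
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "log2 ROR (male vs female)", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier cumulative incidence curves
#'
#' @param km A [km_curve()] tibble.
#' @return A ggplot step plot of cumulative incidence by drug.
#' @export
plot_km <- function(km) {
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$cum_incidence,
                                   colour = .data$drug)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days from therapy start", y = "cumulative incidence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.weibull_fit <- function(object, ...) {
  grid <- seq(0, stats::qweibull(0.99, object$shape_beta, object$scale_alpha),
              length.out = 200)
  df <- tibble(time = grid,
               cum_incidence = stats::pweibull(grid, object$shape_beta,
                                               object$scale_alpha))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cum_incidence)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "days", y = "fitted cumulative incidence") +
    ggplot2::theme_minimal()
}
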