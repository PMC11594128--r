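# ggplot2 views of the main result types.

#' Plot an LD decay profile
#'
#' Mean r-squared per distance bin against bin midpoint, log-scaled distance.
#'
#' @param object an `ld_profile` from [ld_decay_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ld_profile
#' @export
autoplot.ld_profile <- function(object, ...) {
  df <- dplyr::filter(object, .data$n_pairs > 0)
  df$mid_kb <- (df$bin_lo_bp + df$bin_hi_bp) / 2000
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_kb, y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pair distance (kb)", y = expression(mean~r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cross-breed accuracy against LD phase consistency
#'
#' One point per breed pair and heritability: mean validation accuracy of the
#' second population against the pair's consistency.
#'
#' @param results tibble from [run_experiment()] (`cross_pairs` family).
#' @param val_breed_col which validation population to show; default the
#'   breed-B (cross-breed) rows.
#' @return a ggplot.
#' @export
plot_consistency_accuracy <- function(results, val_breed_col = "breed_b") {
  df <- dplyr::filter(results, .data$val_breed == .data[[val_breed_col]])
  agg <- summarize_experiment(df)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$consistency,
                                    y = .data$mean_accuracy,
                                    colour = factor(.data$h2))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "LD phase consistency (cor100)",
                  y = "cross-breed prediction accuracy",
                  colour = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' Accuracy as breed-B individuals join the reference
#'
#' @param results tibble from [run_experiment()] (`added_b` family).
#' @return a ggplot faceted by validated population.
#' @export
plot_added_b <- function(results) {
  agg <- summarize_experiment(results)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$n_ref_b,
                                    y = .data$mean_accuracy,
                                    colour = factor(.data$h2))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$val_breed)) +
    ggplot2::labs(x = "breed-B individuals in the reference",
                  y = "prediction accuracy", colour = expression(h^2)) +
    ggplot2::theme_minimal()
}
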