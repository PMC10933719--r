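#' Plot an abbreviation curve
#'
#' Mean subset-full correlation against subset size, with a 5-95% band
#' across the random draws. Requires ggplot2.
#'
#' @param x a `dd_abbrev` from [abbreviation_analysis()].
#' @return a ggplot object.
#' @export
plot_abbreviation_curve <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  s <- x$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$size, y = .data$mean_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = s$size) +
    ggplot2::labs(
      x = "items in random subset",
      y = "Pearson r with full-scale log k",
      title = sprintf("Scale abbreviation (%s, %s)", x$scale, x$phase)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of two log discounting scores
#'
#' Convergent-validity style scatter of per-person log scores for two
#' (scale, phase) combinations, with the fitted least-squares line.
#'
#' @param estimates a `dd_estimates` data frame.
#' @param scale_x,scale_y,phase_x,phase_y the two scores.
#' @param participants optional analytic-sample restriction.
#' @return a ggplot object.
#' @export
plot_score_scatter <- function(estimates, scale_x, scale_y,
                               phase_x = "phase1", phase_y = "phase1",
                               participants = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  pair <- paired_scores(estimates, scale_x, scale_y, phase_x, phase_y,
                        participants)
  ggplot2::ggplot(pair, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = sprintf("log k (%s, %s)", scale_x, phase_x),
                  y = sprintf("log k (%s, %s)", scale_y, phase_y)) +
    ggplot2::theme_minimal()
}
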