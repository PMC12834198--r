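#' Accuracy trajectories of a federation run
#'
#' Per-participant shared-test accuracy by round, with the weighted
#' ensemble's accuracy overlaid as a dashed line.
#'
#' @param object A `federation_result`.
#' @param metric Metric column to plot (default `"accuracy"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.federation_result <- function(object, metric = "accuracy", ...) {
  m <- tidy(object)
  m$participant_label <- sprintf("P%d (%s)", m$participant, m$model_kind)
  p <- ggplot2::ggplot(
    m,
    ggplot2::aes(x = .data$round, y = .data[[metric]],
                 colour = .data$participant_label)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "federated round", y = paste("shared-test", metric),
      colour = "participant",
      title = "Participant trajectories under soft-label distillation"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$ensemble_metrics) && nrow(object$ensemble_metrics) > 0) {
    p <- p + ggplot2::geom_line(
      data = object$ensemble_metrics,
      ggplot2::aes(x = .data$round, y = .data[[metric]]),
      inherit.aes = FALSE, linetype = "dashed", colour = "black"
    )
  }
  p
}

#' Histogram of bootstrap metric differences
#'
#' @param object A `bootstrap_result`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object with the percentile CI and zero marked.
#' @export
autoplot.bootstrap_result <- function(object, bins = 40, ...) {
  d <- tibble::tibble(delta = object$deltas)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::labs(
      x = sprintf("bootstrap %s difference (A - B)", object$metric),
      y = "resamples",
      title = sprintf("Percentile bootstrap, B = %d", object$B)
    ) +
    ggplot2::theme_minimal()
}

#' Per-round pseudo-label acceptance counts
#'
#' @param result A `federation_result`.
#' @return A ggplot bar chart of accepted pseudo-labels by round.
#' @export
plot_pseudo_acceptance <- function(result) {
  stopifnot(inherits(result, "federation_result"))
  ggplot2::ggplot(
    result$accepted_pseudo,
    ggplot2::aes(x = .data$round, y = .data$accepted_pseudo_count)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "federated round", y = "accepted pseudo-labels",
      title = "Confidence-filtered pseudo-label acceptance"
    ) +
    ggplot2::theme_minimal()
}
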