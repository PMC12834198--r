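#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a federation result
#'
#' One row per round and participant, with the four test-set metrics and
#' the shared-validation accuracy that drove the aggregation weight.
#'
#' @param x A `federation_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.federation_result <- function(x, ...) {
  dplyr::select(
    x$metrics, "round", "participant", "model_kind",
    "accuracy", "precision", "recall", "f1", "validation_accuracy"
  )
}

#' Summarise a federation result per participant
#'
#' The per-participant trajectory summary: round-0 (initial) accuracy,
#' final-round accuracy, mean and SD of accuracy over the federated
#' rounds, and the absolute improvement from round 0 to the final round.
#'
#' @param x A `federation_result`.
#' @param ... Unused.
#' @return A tibble with one row per participant.
#' @export
glance.federation_result <- function(x, ...) {
  m <- x$metrics
  fed <- dplyr::filter(m, .data$round >= 1)
  out <- dplyr::summarise(
    dplyr::group_by(fed, .data$participant, .data$model_kind),
    final_accuracy = .data$accuracy[which.max(.data$round)],
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = stats::sd(.data$accuracy),
    .groups = "drop"
  )
  init <- dplyr::select(
    dplyr::filter(m, .data$round == 0L),
    "participant",
    initial_accuracy = "accuracy"
  )
  out <- dplyr::left_join(out, init, by = "participant")
  dplyr::mutate(
    out,
    improvement = .data$final_accuracy - .data$initial_accuracy
  )
}

#' Tidy a bootstrap comparison
#'
#' Broom-style one-row summary: the mean metric difference with its
#' percentile confidence bounds.
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A one-row tibble: `metric`, `estimate` (mean delta),
#'   `conf.low`, `conf.high`, `mean_a`, `mean_b`.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    estimate = x$mean_delta,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    mean_a = x$mean_a,
    mean_b = x$mean_b
  )
}

#' Glance at a bootstrap comparison
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A one-row tibble: `B`, `n`, `alpha`, `significant`.
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(B = x$B, n = x$n, alpha = x$alpha,
                 significant = x$significant)
}

#' Tidy a ledger audit
#'
#' @param x A `ledger_audit`.
#' @param ... Unused.
#' @return One row per rejection reason plus the accepted row, with
#'   counts; column `share_pct` is the percentage of all transactions.
#' @export
tidy.ledger_audit <- function(x, ...) {
  out <- tibble::tibble(
    status = c("accepted", rep("rejected", length(x$rejected_by_reason))),
    reason = c("", names(x$rejected_by_reason)),
    count = c(x$valid, as.integer(x$rejected_by_reason))
  )
  dplyr::mutate(
    out,
    share_pct = if (x$total > 0) round(100 * .data$count / x$total, 2) else 0
  )
}
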