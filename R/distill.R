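#' Distillation configuration
#'
#' Constants of the soft-label distillation chain. Defaults are the
#' framework's stated operating point: temperature `T = 2` (smooths
#' overconfident rows before aggregation), confidence threshold
#' `tau = 0.7` (a consensus row becomes a pseudo-label only when its
#' maximum probability reaches tau), aggregation weight cap 0.5 (no
#' participant may dominate the ensemble), and a probability floor used
#' when reconstructing logits from probability rows.
#'
#' @param temperature Softening temperature T > 0.
#' @param tau Confidence threshold in (0.5, 1].
#' @param weight_cap Upper bound on any aggregation weight, in (1/N, 1].
#' @param epsilon Probability floor for logit reconstruction.
#' @return A list of class `distill_config`.
#' @export
distill_config <- function(temperature = 2, tau = 0.7,
                           weight_cap = 0.5, epsilon = 1e-12) {
  if (!is.numeric(temperature) || !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a finite positive number")
  }
  if (tau <= 0.5 || tau > 1) stop("`tau` must lie in (0.5, 1]")
  if (weight_cap <= 0 || weight_cap > 1) stop("`weight_cap` must lie in (0, 1]")
  stopifnot(epsilon > 0)
  structure(
    list(
      temperature = temperature, tau = tau,
      weight_cap = weight_cap, epsilon = epsilon
    ),
    class = "distill_config"
  )
}

#' Temperature-scale soft-label rows
#'
#' Per row: logits are reconstructed as `log(p + epsilon)`, divided by
#' `T`, passed through the softmax and renormalized. `T = 1` is the
#' identity (up to the epsilon floor); `T > 1` smooths rows towards
#' uniform and never increases a row's maximum probability.
#'
#' @param probs Matrix of class-probability rows.
#' @param temperature T > 0.
#' @param epsilon Probability floor.
#' @return Matrix of the same shape; rows sum to 1.
#' @examples
#' temperature_scale(rbind(c(0.9, 0.1)), temperature = 2)
#' @export
temperature_scale <- function(probs, temperature = 2, epsilon = 1e-12) {
  if (!is.numeric(temperature) || !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a finite positive number")
  }
  probs <- as.matrix(probs)
  logits <- log(probs + epsilon) / temperature
  logits <- logits - apply(logits, 1L, max)   # overflow guard
  e <- exp(logits)
  out <- e / rowSums(e)
  dimnames(out) <- dimnames(probs)
  out
}

#' Accuracy-proportional aggregation weights
#'
#' Each participant's weight is its shared-validation accuracy divided by
#' the sum of all accuracies, so weights are non-negative and sum to 1.
#'
#' @param accuracies Non-negative accuracies, at least one positive.
#' @return Numeric weight vector summing to 1.
#' @examples
#' compute_weights(c(50, 5, 30, 10, 5))
#' @export
compute_weights <- function(accuracies) {
  accuracies <- as.numeric(accuracies)
  if (any(!is.finite(accuracies)) || any(accuracies < 0)) {
    stop("accuracies must be finite and non-negative")
  }
  total <- sum(accuracies)
  if (total <= 0) stop("all accuracies are zero; weights are undefined")
  accuracies / total
}

#' Clip aggregation weights at a cap and renormalize
#'
#' Proportional water-filling: weights above the cap are set to the cap
#' and the excess is redistributed proportionally among the unclipped
#' weights, iterating until every weight is at most the cap. The sum
#' stays 1 and the weight ordering is preserved. `cap = 1/N` forces the
#' uniform vector.
#'
#' @param weights Weight vector summing to 1.
#' @param cap Upper bound, at least `1/length(weights)`.
#' @return Clipped weight vector summing to 1.
#' @examples
#' clip_weights(c(0.7, 0.2, 0.1), cap = 0.5)
#' @export
clip_weights <- function(weights, cap = 0.5) {
  weights <- as.numeric(weights)
  n <- length(weights)
  if (cap < 1 / n - 1e-12) {
    stop("`cap` below 1/N makes a sum-1 weight vector infeasible")
  }
  w <- weights / sum(weights)
  repeat {
    over <- w > cap + 1e-15
    if (!any(over)) break
    excess <- sum(w[over] - cap)
    w[over] <- cap
    free <- !over & w > 0
    if (!any(free)) {
      w[] <- pmin(w + excess / n, cap)
      break
    }
    w[free] <- w[free] + excess * w[free] / sum(w[free])
  }
  w / sum(w)
}

#' Weighted soft-vote aggregation
#'
#' Row-wise convex combination of the participants' soft-label matrices:
#' the global probability row is the weight-weighted sum of the
#' individual rows.
#'
#' @param soft_labels List of `n x C` probability matrices sharing shape
#'   and instance order.
#' @param weights Weight vector, one per matrix, summing to 1.
#' @return `n x C` matrix of global probabilities.
#' @export
aggregate_soft <- function(soft_labels, weights) {
  stopifnot(is.list(soft_labels), length(soft_labels) >= 1)
  if (length(weights) != length(soft_labels)) {
    stop("`weights` length must match the number of soft-label matrices")
  }
  dims <- lapply(soft_labels, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all soft-label matrices must share the same shape")
  }
  weights <- weights / sum(weights)
  out <- Reduce(
    `+`,
    Map(function(m, w) w * as.matrix(m), soft_labels, weights)
  )
  out / rowSums(out)
}

#' Filter confident consensus rows into pseudo-labels
#'
#' A consensus row is accepted when its maximum probability is at least
#' `tau` (inclusive). Accepted rows yield a hard pseudo-label from the
#' argmax, taking the lowest class index on exact ties; rejected rows
#' carry no label.
#'
#' @param probs Global probability matrix.
#' @param tau Confidence threshold.
#' @return List with `accepted` (logical mask), `labels` (integer 0-based
#'   class for accepted rows, `NA` elsewhere), `indices` (accepted row
#'   numbers).
#' @examples
#' filter_confident(rbind(c(0.70, 0.30), c(0.69, 0.31)), tau = 0.7)
#' @export
filter_confident <- function(probs, tau = 0.7) {
  probs <- as.matrix(probs)
  rowmax <- apply(probs, 1L, max)
  accepted <- rowmax >= tau
  labels <- rep(NA_integer_, nrow(probs))
  labels[accepted] <- max.col(probs[accepted, , drop = FALSE],
                              ties.method = "first") - 1L
  list(accepted = accepted, labels = labels, indices = which(accepted))
}
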