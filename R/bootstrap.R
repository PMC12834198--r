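#' Percentile-bootstrap comparison of two prediction vectors
#'
#' Compares two classifiers' hard predictions on the same held-out test
#' set. For each of `B` resamples of test instances drawn with
#' replacement, the chosen metric is computed for both prediction vectors
#' on the resampled truth and their difference `delta(b) = M_A(b) -
#' M_B(b)` recorded; the `1 - alpha` confidence interval is the empirical
#' `(alpha/2, 1 - alpha/2)` percentile pair of the `B` differences. The
#' difference is declared significant (two-sided) when the interval
#' excludes zero.
#'
#' @param preds_a,preds_b Hard 0/1 predictions of the two pipelines.
#' @param truth True 0/1 labels, same length.
#' @param metric One of `"accuracy"`, `"precision"`, `"recall"`, `"f1"`.
#' @param B Number of bootstrap resamples (default 1000).
#' @param alpha Two-sided significance level (default 0.05).
#' @param seed Integer seed for the resampling.
#' @return An object of class `bootstrap_result` with elements `deltas`,
#'   `ci_low`, `ci_high`, `mean_delta`, `mean_a`, `mean_b`,
#'   `significant`, `metric`, `B`, `alpha`, `n`.
#' @examples
#' truth <- rep(c(0, 1), 50)
#' bootstrap_compare(truth, rev(truth), truth, B = 200, seed = 1)
#' @export
bootstrap_compare <- function(preds_a, preds_b, truth,
                              metric = c("accuracy", "precision", "recall", "f1"),
                              B = 1000L, alpha = 0.05, seed = 1L) {
  metric <- match.arg(metric)
  preds_a <- as.integer(preds_a)
  preds_b <- as.integer(preds_b)
  truth <- as.integer(truth)
  n <- length(truth)
  if (length(preds_a) != n || length(preds_b) != n) {
    stop("`preds_a`, `preds_b` and `truth` must have equal length")
  }
  stopifnot(B >= 1)

  metric_fn <- function(pred, tr) {
    if (metric == "accuracy") {
      return(mean(pred == tr))
    }
    evaluate_predictions(pred, tr)[[metric]]
  }

  with_preserved_seed(seed, {
    ma <- numeric(B)
    mb <- numeric(B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      ma[b] <- metric_fn(preds_a[idx], truth[idx])
      mb[b] <- metric_fn(preds_b[idx], truth[idx])
    }
    deltas <- ma - mb
    ci <- stats::quantile(deltas, c(alpha / 2, 1 - alpha / 2),
                          names = FALSE, type = 7)
    structure(
      list(
        deltas = deltas, ci_low = ci[1], ci_high = ci[2],
        mean_delta = mean(deltas), mean_a = mean(ma), mean_b = mean(mb),
        significant = ci[1] > 0 || ci[2] < 0,
        metric = metric, B = as.integer(B), alpha = alpha, n = n
      ),
      class = "bootstrap_result"
    )
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> %s: mean A %.4f, mean B %.4f\n", x$metric,
    x$mean_a, x$mean_b
  ))
  cat(sprintf(
    "  delta %.4f, %d%% percentile CI [%.4f, %.4f] (B=%d, n=%d) -> %s\n",
    x$mean_delta, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
    x$B, x$n,
    if (x$significant) "significant" else "not significant"
  ))
  invisible(x)
}
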