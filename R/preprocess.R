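#' Preprocessing configuration
#'
#' Bundles the tunable constants of the preprocessing chain: the IQR
#' fence multiplier, the local-outlier-factor neighbourhood size and
#' score threshold, the glucose/insulin bin edges, the SMOTE
#' neighbourhood size, and the ceiling on the fraction of rows outlier
#' screening may remove before a data-quality warning fires.
#'
#' Glucose edges (140, 200 mg/dL) follow the standard clinical cut-offs
#' between normoglycemia, impaired tolerance and diabetes. Insulin edges
#' default to `NULL`, meaning training-data quartiles are used.
#'
#' @param iqr_multiplier Positive fence multiplier (default 1.5).
#' @param lof_neighbors Neighbourhood size k for LOF (default 20).
#' @param lof_threshold LOF score above which a row is flagged (default 1.5).
#' @param glucose_bin_edges Strictly ascending edges, mg/dL.
#' @param insulin_bin_edges Strictly ascending edges, uU/mL, or `NULL`
#'   for training-data quartiles.
#' @param smote_k SMOTE nearest-neighbour count (default 5).
#' @param max_outlier_frac Warning ceiling on removed-row fraction (default 0.10).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(iqr_multiplier = 1.5, lof_neighbors = 20L,
                              lof_threshold = 1.5,
                              glucose_bin_edges = c(140, 200),
                              insulin_bin_edges = NULL,
                              smote_k = 5L, max_outlier_frac = 0.10) {
  stopifnot(iqr_multiplier > 0, lof_neighbors >= 1, lof_threshold > 0,
            smote_k >= 1, max_outlier_frac > 0)
  if (is.unsorted(glucose_bin_edges, strictly = TRUE)) {
    stop("glucose_bin_edges must be strictly ascending")
  }
  if (!is.null(insulin_bin_edges) &&
      is.unsorted(insulin_bin_edges, strictly = TRUE)) {
    stop("insulin_bin_edges must be strictly ascending")
  }
  structure(
    list(
      iqr_multiplier = iqr_multiplier,
      lof_neighbors = as.integer(lof_neighbors),
      lof_threshold = lof_threshold,
      glucose_bin_edges = glucose_bin_edges,
      insulin_bin_edges = insulin_bin_edges,
      smote_k = as.integer(smote_k),
      max_outlier_frac = max_outlier_frac
    ),
    class = "preprocess_config"
  )
}

#' Flag outliers by the interquartile-range rule
#'
#' A value is flagged when it falls below `Q1 - multiplier * IQR` or above
#' `Q3 + multiplier * IQR`, with quartiles computed by linear
#' interpolation (`stats::quantile()` type 7). A constant column has zero
#' IQR and yields an all-`FALSE` mask.
#'
#' @param column Numeric vector (length >= 4).
#' @param multiplier Positive fence multiplier.
#' @return Logical mask, `TRUE` at flagged positions.
#' @export
flag_outliers_iqr <- function(column, multiplier = 1.5) {
  stopifnot(is.numeric(column), length(column) >= 4, multiplier > 0)
  q <- stats::quantile(column, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  column < q[1] - multiplier * iqr | column > q[2] + multiplier * iqr
}

#' Flag outliers by local outlier factor
#'
#' Computes the classical LOF score for every row — the ratio of the
#' average local reachability density of a row's k nearest neighbours
#' (Euclidean metric) to its own — and flags rows whose score exceeds
#' `threshold`. Points in uniform-density regions (including exact
#' duplicates) score ~1 and are never flagged.
#'
#' @param features Numeric matrix (rows = observations); `k < nrow`.
#' @param k Neighbourhood size.
#' @param threshold LOF score cut-off (default 1.5).
#' @return Logical mask of length `nrow(features)`.
#' @export
flag_outliers_lof <- function(features, k = 20L, threshold = 1.5) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k >= n) stop("`k` must be smaller than the number of rows")
  lof_scores(features, k) > threshold
}

# Brute-force LOF (Breunig et al. construction) on a full distance matrix;
# adequate at simulator scale (n up to a few thousand).
lof_scores <- function(features, k) {
  n <- nrow(features)
  d <- as.matrix(stats::dist(features))
  diag(d) <- Inf
  ord <- apply(d, 1L, order)           # n x n, column i = neighbours of i
  # k-distance with distance ties included in the neighbourhood
  kdist <- numeric(n)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, ord[, i]]
    kdist[i] <- di[k]
    neigh[[i]] <- ord[, i][d[i, ord[, i]] <= kdist[i] + 1e-12]
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- neigh[[i]]
    reach <- pmax(kdist[nb], d[i, nb])
    lrd[i] <- length(nb) / sum(reach)
  }
  vapply(seq_len(n), function(i) mean(lrd[neigh[[i]]]) / lrd[i], numeric(1))
}

#' Append ordinal glucose and insulin bin columns
#'
#' Adds `glucose_bin` and `insulin_bin` ordinal columns (0-based,
#' left-closed intervals: a value equal to an edge falls in the upper
#' bin). Original columns are untouched. Insulin edges default to the
#' quartiles of the rows indexed by `fit_rows` when the config leaves
#' them `NULL`.
#'
#' @param cohort A cohort tibble.
#' @param config A [preprocess_config()].
#' @param fit_rows Rows used to derive data-driven insulin edges
#'   (default: all rows).
#' @return The cohort with two appended integer bin columns.
#' @export
engineer_bins <- function(cohort, config = preprocess_config(),
                          fit_rows = seq_len(nrow(cohort))) {
  validate_cohort(cohort)
  insulin_edges <- config$insulin_bin_edges
  if (is.null(insulin_edges)) {
    insulin_edges <- unique(stats::quantile(
      cohort$insulin[fit_rows], c(0.25, 0.5, 0.75), names = FALSE, type = 7
    ))
  }
  dplyr::mutate(
    cohort,
    glucose_bin = bin_ordinal(.data$glucose, config$glucose_bin_edges),
    insulin_bin = bin_ordinal(.data$insulin, insulin_edges)
  )
}

# Left-closed ordinal binning: bin = number of edges <= value.
bin_ordinal <- function(x, edges) {
  as.integer(findInterval(x, edges, left.open = FALSE))
}

#' Z-score normalization fitted on a row subset
#'
#' Column moments are computed on `fit_rows` only and applied to the full
#' matrix, so shared validation/test rows never leak into the fit. A
#' zero-variance column maps to all zeros.
#'
#' @param features Numeric matrix or data frame of features.
#' @param fit_rows Indices of rows used to estimate means and SDs.
#' @return List with `transformed` (matrix), `center` and `scale`
#'   (named numeric vectors).
#' @export
zscore_fit <- function(features, fit_rows = seq_len(nrow(features))) {
  features <- as.matrix(features)
  stopifnot(length(fit_rows) >= 1)
  center <- colMeans(features[fit_rows, , drop = FALSE])
  scale <- apply(features[fit_rows, , drop = FALSE], 2L, stats::sd)
  if (length(fit_rows) == 1L) scale[] <- 0
  list(
    transformed = zscore_apply(features, center, scale),
    center = center,
    scale = scale
  )
}

#' @rdname zscore_fit
#' @param center,scale Moments previously returned by `zscore_fit()`.
#' @export
zscore_apply <- function(features, center, scale) {
  features <- as.matrix(features)
  out <- sweep(features, 2L, center, "-")
  safe <- ifelse(scale > 0, scale, 1)
  out <- sweep(out, 2L, safe, "/")
  out[, scale == 0] <- 0
  out
}

#' Balance classes with SMOTE
#'
#' Equalizes class counts by synthetic minority oversampling: each
#' synthetic record is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`,
#' where `x` is a minority record and `x_nn` one of its `k` nearest
#' minority neighbours (Euclidean). Original rows are preserved verbatim
#' and synthetic rows are appended after them.
#'
#' @param features Numeric matrix.
#' @param labels Binary 0/1 vector, one per row.
#' @param k Number of minority neighbours to interpolate towards; must be
#'   below the minority class count.
#' @param seed Integer seed.
#' @return List with `features` (augmented matrix) and `labels`.
#' @export
smote_balance <- function(features, labels, k = 5L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0L, 1L)))
  counts <- tabulate(labels + 1L, 2L)
  if (counts[1] == counts[2]) {
    return(list(features = features, labels = labels))
  }
  minority <- if (counts[1] < counts[2]) 0L else 1L
  min_idx <- which(labels == minority)
  n_min <- length(min_idx)
  if (n_min <= k) {
    stop("minority class count (", n_min, ") must exceed k (", k, ")")
  }
  n_new <- abs(counts[1] - counts[2])

  xm <- features[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- matrix(
    apply(d, 1L, function(row) order(row)[seq_len(k)]),
    nrow = k
  )  # k x n_min

  with_preserved_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- vapply(base, function(b) nn[sample.int(k, 1L), b], integer(1))
    u <- stats::runif(n_new)
    synth <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    list(
      features = rbind(features, synth),
      labels = c(labels, rep(minority, n_new))
    )
  })
}

#' Remove outlying rows before partitioning
#'
#' Applies the union of the per-column IQR rule (any feature column) and
#' the multivariate LOF rule, drops flagged rows, and warns when more
#' than `config$max_outlier_frac` of the cohort would be removed.
#'
#' @param cohort A cohort tibble.
#' @param config A [preprocess_config()].
#' @return List with `cohort` (cleaned), `removed` (original row
#'   indices), `mask` (logical flag vector).
#' @export
remove_outliers <- function(cohort, config = preprocess_config()) {
  validate_cohort(cohort)
  feats <- as.matrix(cohort[cohort_feature_names()])
  iqr_mask <- Reduce(`|`, lapply(
    seq_len(ncol(feats)),
    function(j) flag_outliers_iqr(feats[, j], config$iqr_multiplier)
  ))
  lof_mask <- flag_outliers_lof(feats, config$lof_neighbors, config$lof_threshold)
  mask <- iqr_mask | lof_mask
  frac <- mean(mask)
  if (frac > config$max_outlier_frac) {
    warning(sprintf(
      "outlier screening flagged %.1f%% of rows (ceiling %.0f%%); check data quality",
      100 * frac, 100 * config$max_outlier_frac
    ))
  }
  list(
    cohort = cohort[!mask, , drop = FALSE],
    removed = which(mask),
    mask = mask
  )
}
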