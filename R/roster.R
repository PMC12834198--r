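#' The five-participant reference roster
#'
#' Returns the heterogeneous roster used throughout the simulator: five
#' participants spanning resource levels from a large hospital down to a
#' personal health tracker, each with a model family and hyperparameters
#' matched to its capacity, a share of the training pool (`data_fraction`)
#' and a static aggregation weight used before any validation accuracy
#' exists.
#'
#' @return A tibble with one row per participant: `id`, `name`,
#'   `model_kind`, `hyperparameters` (list column), `data_fraction`,
#'   `resource_level`, `static_weight`.
#' @examples
#' default_roster()
#' @export
default_roster <- function() {
  roster <- tibble::tibble(
    id = 1:5,
    name = c(
      "Large hospital", "Urban health kiosk", "Regional clinic",
      "Community health clinic", "Personal health tracker"
    ),
    model_kind = c(
      "random_forest", "knn", "gradient_boosted_trees",
      "decision_tree", "linear_svm"
    ),
    hyperparameters = list(
      list(n_estimators = 130L, max_depth = 15L, max_features = 0.75),
      list(n_neighbors = 5L),
      list(learning_rate = 0.01, max_depth = 10L, n_estimators = 180L),
      list(criterion = "gini", max_depth = Inf),
      list(kernel = "linear", cost = 1.0)
    ),
    data_fraction = c(0.50, 0.05, 0.30, 0.10, 0.05),
    resource_level = c("very_high", "low", "high", "medium", "very_low"),
    static_weight = c(0.50, 0.05, 0.30, 0.10, 0.05)
  )
  validate_roster(roster)
}

#' Validate a participant roster
#'
#' Checks the roster contract: recognised model kinds, data fractions in
#' (0, 1] summing to at most 1, static weights summing to 1.
#'
#' @param roster A roster tibble as returned by [default_roster()].
#' @return The roster, invisibly.
#' @export
validate_roster <- function(roster) {
  needed <- c(
    "id", "name", "model_kind", "hyperparameters",
    "data_fraction", "resource_level", "static_weight"
  )
  missing <- setdiff(needed, names(roster))
  if (length(missing) > 0) {
    stop("roster is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(roster) < 1) stop("roster must have at least one participant")
  if (anyDuplicated(roster$id)) stop("participant ids must be unique")
  known <- c(
    "random_forest", "knn", "gradient_boosted_trees",
    "decision_tree", "linear_svm"
  )
  bad <- setdiff(roster$model_kind, known)
  if (length(bad) > 0) {
    stop("unknown model_kind: ", paste(bad, collapse = ", "))
  }
  if (any(roster$data_fraction <= 0 | roster$data_fraction > 1)) {
    stop("data fractions must lie in (0, 1]")
  }
  if (sum(roster$data_fraction) > 1 + 1e-9) {
    stop("data fractions must sum to at most 1")
  }
  if (abs(sum(roster$static_weight) - 1) > 1e-9) {
    stop("static weights must sum to 1")
  }
  invisible(roster)
}
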