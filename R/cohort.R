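#' Column names of the diabetes-cohort schema
#'
#' The eight clinical attributes of the classic diabetes tabular schema,
#' in canonical order, plus the binary `outcome` column appended by
#' [generate_cohort()].
#'
#' @return Character vector of the eight feature column names.
#' @export
cohort_feature_names <- function() {
  c(
    "pregnancies", "glucose", "blood_pressure", "skin_thickness",
    "insulin", "bmi", "pedigree", "age"
  )
}

# Class-conditional location shifts applied to positives at effect_scale = 1.
# Chosen once to emulate the separability of real diabetes screening data
# (combined Mahalanobis distance ~1.9, Bayes accuracy ~0.84).
.cohort_shifts <- c(glucose = 32, bmi = 4.5, age = 8, pedigree = 0.18)

#' Generate a synthetic diabetes-style cohort
#'
#' Draws a cohort of `n` records emulating the schema of the public
#' diabetes screening dataset (768 female patients, 8 clinical attributes,
#' binary outcome): pregnancy count, plasma glucose (mg/dL), diastolic
#' blood pressure (mmHg), triceps skin-fold thickness (mm), serum insulin
#' (uU/mL), body-mass index (kg/m^2), diabetes pedigree function and age
#' (years). Labels are Bernoulli with probability `prevalence`; positives
#' have glucose, BMI, age and pedigree shifted upward by
#' `effect_scale` times a fixed clinical shift, so `effect_scale = 0`
#' yields label-independent features (zero signal) and `effect_scale = 1`
#' yields a separability comparable to real screening data.
#'
#' Identical `(n, prevalence, effect_scale, seed)` give bit-identical
#' output; the caller's RNG state is left untouched.
#'
#' @param n Number of records (>= 1).
#' @param prevalence Expected positive fraction, strictly in (0, 1).
#' @param effect_scale Non-negative multiplier on the class-conditional
#'   mean shifts. 0 removes all label signal.
#' @param seed Integer seed controlling every draw.
#' @return A tibble with the eight feature columns and an integer
#'   `outcome` column in \{0, 1\}.
#' @examples
#' cohort <- generate_cohort(200, prevalence = 0.35, effect_scale = 1, seed = 1)
#' mean(cohort$outcome)
#' @export
generate_cohort <- function(n, prevalence = 0.35, effect_scale = 1, seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1, is.finite(n), n >= 1)
  if (!is.numeric(prevalence) || !is.finite(prevalence) ||
      prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must be a finite number strictly between 0 and 1.")
  }
  if (!is.numeric(effect_scale) || !is.finite(effect_scale) || effect_scale < 0) {
    stop("`effect_scale` must be a finite non-negative number.")
  }
  n <- as.integer(n)

  with_preserved_seed(seed, {
    outcome <- stats::rbinom(n, 1L, prevalence)
    # Guarantee both classes for usable cohorts; flip one record if needed.
    if (n >= 20) {
      if (sum(outcome) == 0L) outcome[1L] <- 1L
      if (sum(outcome) == n) outcome[1L] <- 0L
    }
    es <- effect_scale
    sh <- .cohort_shifts
    cohort <- tibble::tibble(
      pregnancies = stats::rpois(n, 3),
      glucose = pmax(40, stats::rnorm(n, 110, 24)) + es * sh[["glucose"]] * outcome,
      blood_pressure = pmax(30, stats::rnorm(n, 70, 12)),
      skin_thickness = pmax(5, stats::rnorm(n, 27, 10)),
      insulin = stats::rlnorm(n, log(80), 0.5),
      bmi = pmax(15, stats::rnorm(n, 30.5, 6)) + es * sh[["bmi"]] * outcome,
      pedigree = stats::rlnorm(n, log(0.4), 0.5) + es * sh[["pedigree"]] * outcome,
      age = 21 + stats::rgamma(n, shape = 2, scale = 5.5) + es * sh[["age"]] * outcome,
      outcome = as.integer(outcome)
    )
    validate_cohort(cohort)
    cohort
  })
}

#' Validate a cohort data frame
#'
#' Checks the schema produced by [generate_cohort()] (or read from CSV):
#' the eight feature columns, a binary `outcome`, no missing values.
#'
#' @param cohort A data frame to check.
#' @return The cohort, invisibly, as a tibble.
#' @export
validate_cohort <- function(cohort) {
  needed <- c(cohort_feature_names(), "outcome")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(cohort) < 1) stop("cohort must have at least one record")
  if (anyNA(cohort[needed])) stop("cohort contains missing values")
  if (!all(cohort$outcome %in% c(0L, 1L))) {
    stop("`outcome` must be binary 0/1")
  }
  invisible(tibble::as_tibble(cohort))
}

#' Read / write a cohort as CSV
#'
#' The CSV interchange format has a header row with the eight feature
#' names plus `outcome`, so the real screening dataset can be adapted by
#' renaming its columns.
#'
#' @param path File path.
#' @param cohort A validated cohort tibble.
#' @return `read_cohort_csv()` returns a validated cohort tibble;
#'   `write_cohort_csv()` returns `cohort` invisibly.
#' @export
read_cohort_csv <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  cohort$outcome <- as.integer(cohort$outcome)
  validate_cohort(cohort)
  tibble::as_tibble(cohort)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(cohort)
}

# Run `code` under a fixed seed without disturbing the caller's RNG.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
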