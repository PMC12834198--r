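#' Partition a cohort across participants with controllable label skew
#'
#' Splits cohort indices into three shared, label-stratified subsets —
#' a validation set (participant accuracies are measured there), a test
#' set (reported metrics) and an unlabeled pool (soft labels are
#' exchanged on it) — and distributes the remaining records as disjoint
#' per-participant training shards sized by each participant's
#' `data_fraction`.
#'
#' Shard label composition follows the standard Dirichlet non-IID
#' construction: each shard's positive-class proportion is drawn from the
#' two-class Dirichlet (a Beta) with concentration `1/skew` around the
#' global prevalence. `skew = 0` short-circuits to IID assignment; larger
#' `skew` makes shards increasingly label-imbalanced. Shard and shared-set
#' sizes are rounded by the largest-remainder method so totals are
#' conserved.
#'
#' @param cohort A validated cohort tibble.
#' @param roster A participant roster (see [default_roster()]).
#' @param skew Non-negative label-skew intensity; 0 = IID.
#' @param val_frac,test_frac,pool_frac Fractions of the cohort reserved
#'   for the shared validation, test and unlabeled-pool sets; their sum
#'   must be below 1.
#' @param seed Integer seed.
#' @return An object of class `federation_partition`: a list with
#'   `shards` (named list of integer index vectors, one per participant
#'   id), `validation`, `test`, `unlabeled_pool`, and the generating
#'   parameters.
#' @examples
#' cohort <- generate_cohort(500, seed = 1)
#' part <- partition_non_iid(cohort, default_roster(), skew = 1, seed = 1)
#' lengths(part$shards)
#' @export
partition_non_iid <- function(cohort, roster, skew = 1,
                              val_frac = 0.15, test_frac = 0.15,
                              pool_frac = 0.20, seed = 1L) {
  validate_cohort(cohort)
  validate_roster(roster)
  fracs <- c(val_frac, test_frac, pool_frac)
  if (any(!is.finite(fracs)) || any(fracs < 0) || sum(fracs) >= 1) {
    stop("val_frac + test_frac + pool_frac must be non-negative and sum below 1")
  }
  if (!is.finite(skew) || skew < 0) stop("`skew` must be finite and non-negative")

  n <- nrow(cohort)
  labels <- cohort$outcome

  with_preserved_seed(seed, {
    # Stratified shared sets: allocate within each class by largest remainder.
    shared <- list(validation = integer(0), test = integer(0),
                   unlabeled_pool = integer(0))
    remaining <- integer(0)
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      sizes <- largest_remainder(length(idx) * fracs)
      cuts <- cumsum(sizes)
      shared$validation <- c(shared$validation, idx[seq_len(sizes[1])])
      shared$test <- c(shared$test, idx[seq2(cuts[1] + 1, cuts[2])])
      shared$unlabeled_pool <- c(shared$unlabeled_pool, idx[seq2(cuts[2] + 1, cuts[3])])
      remaining <- c(remaining, idx[seq2(cuts[3] + 1, length(idx))])
    }
    shared <- lapply(shared, sort)

    shards <- assign_shards(remaining, labels[remaining], roster, skew)
    structure(
      list(
        shards = shards,
        validation = shared$validation,
        test = shared$test,
        unlabeled_pool = shared$unlabeled_pool,
        skew = skew, val_frac = val_frac, test_frac = test_frac,
        pool_frac = pool_frac, seed = as.integer(seed), n = n
      ),
      class = "federation_partition"
    )
  })
}

# Distribute `pool` indices (with labels `pool_labels`) into shards sized by
# data fractions, with per-shard positive proportions drawn from the 2-class
# Dirichlet with concentration 1/skew.
assign_shards <- function(pool, pool_labels, roster, skew) {
  sizes <- largest_remainder(length(pool) * roster$data_fraction)
  n_shards <- length(sizes)
  pos_pool <- sample(pool[pool_labels == 1L])
  neg_pool <- sample(pool[pool_labels == 0L])
  prev <- length(pos_pool) / max(1L, length(pool))

  if (skew <= 0 || prev == 0 || prev == 1) {
    target_prop <- rep(prev, n_shards)
  } else {
    conc <- 1 / skew
    target_prop <- stats::rbeta(n_shards, prev * conc, (1 - prev) * conc)
  }

  # Positive counts: largest-remainder on the target composition, then
  # repair to feasibility (cannot exceed shard size or available positives).
  want <- target_prop * sizes
  total_pos <- min(length(pos_pool), sum(sizes))
  pos_counts <- if (sum(want) > 0) {
    largest_remainder(want / sum(want) * min(round(sum(want)), total_pos))
  } else {
    rep(0L, n_shards)
  }
  pos_counts <- pmin(pos_counts, sizes)
  # Redistribute any shortfall/excess against the negative supply.
  deficit <- sum(sizes) - sum(pos_counts) - length(neg_pool)
  i <- 1L
  while (deficit > 0 && i <= n_shards) {
    room <- min(deficit, sizes[i] - pos_counts[i], length(pos_pool) - sum(pos_counts))
    pos_counts[i] <- pos_counts[i] + max(0L, room)
    deficit <- sum(sizes) - sum(pos_counts) - length(neg_pool)
    i <- i + 1L
  }

  # Degenerate-shard guard: a trainable binary shard needs both classes.
  # When supply allows, shift one record from the best-stocked shard so no
  # shard of size >= 4 is single-class.
  for (i in seq_len(n_shards)) {
    if (sizes[i] >= 4L) {
      if (pos_counts[i] == 0L && sum(pos_counts) > 0) {
        donor <- which.max(pos_counts)
        if (pos_counts[donor] > 1L) {
          pos_counts[donor] <- pos_counts[donor] - 1L
          pos_counts[i] <- 1L
        }
      }
      if (sizes[i] - pos_counts[i] == 0L && sum(sizes - pos_counts) > 0) {
        donor <- which.max(sizes - pos_counts)
        if (sizes[donor] - pos_counts[donor] > 1L) {
          pos_counts[donor] <- pos_counts[donor] + 1L
          pos_counts[i] <- pos_counts[i] - 1L
        }
      }
    }
  }

  shards <- vector("list", n_shards)
  names(shards) <- as.character(roster$id)
  p_at <- 1L
  n_at <- 1L
  for (i in seq_len(n_shards)) {
    np <- pos_counts[i]
    nn <- sizes[i] - np
    shards[[i]] <- sort(c(
      pos_pool[seq2(p_at, p_at + np - 1L)],
      neg_pool[seq2(n_at, n_at + nn - 1L)]
    ))
    p_at <- p_at + np
    n_at <- n_at + nn
  }
  shards
}

# Integer apportionment conserving round(sum(x)) (largest-remainder method).
largest_remainder <- function(x) {
  total <- round(sum(x))
  base <- floor(x)
  short <- total - sum(base)
  if (short > 0) {
    order_rem <- order(x - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  } else if (short < 0) {
    order_rem <- order(x - base)
    take <- order_rem[seq_len(-short)]
    base[take] <- pmax(0, base[take] - 1)
  }
  as.integer(base)
}

# seq() that is empty when from > to (avoids the 1:0 trap).
seq2 <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}

#' @export
print.federation_partition <- function(x, ...) {
  cat("<federation_partition>\n")
  cat("  cohort size:", x$n, "\n")
  cat("  shards:", paste(sprintf("%s=%d", names(x$shards), lengths(x$shards)),
                         collapse = ", "), "\n")
  cat(sprintf(
    "  shared: validation=%d test=%d unlabeled_pool=%d (skew=%g)\n",
    length(x$validation), length(x$test), length(x$unlabeled_pool), x$skew
  ))
  invisible(x)
}

#' Serialize / restore a partition as JSON index lists
#'
#' @param partition A `federation_partition`.
#' @param path File path for the JSON representation.
#' @return `read_partition_json()` returns a `federation_partition`;
#'   `write_partition_json()` returns the partition invisibly.
#' @export
write_partition_json <- function(partition, path) {
  stopifnot(inherits(partition, "federation_partition"))
  jsonlite::write_json(unclass(partition), path, auto_unbox = TRUE, digits = NA)
  invisible(partition)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$shards <- lapply(raw$shards, as.integer)
  for (f in c("validation", "test", "unlabeled_pool")) raw[[f]] <- as.integer(raw[[f]])
  structure(raw, class = "federation_partition")
}
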