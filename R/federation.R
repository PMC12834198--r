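#' Initialise a federation from a cohort
#'
#' Runs the data pipeline once — outlier screening (IQR + LOF union),
#' non-IID partitioning, glucose/insulin binning and z-scoring fitted on
#' the training shards only, per-shard SMOTE balancing — registers every
#' participant, the validators and the aggregator on a fresh trust
#' ledger, then performs round-0 training (shards only, no pseudo-labels)
#' and evaluation on the shared test set.
#'
#' @param cohort A validated cohort tibble.
#' @param roster Participant roster (default [default_roster()]).
#' @param skew Non-IID label-skew intensity passed to
#'   [partition_non_iid()].
#' @param dconfig A [distill_config()].
#' @param pconfig A [preprocess_config()].
#' @param n_validators Number of validator nodes registered (default 3).
#' @param quorum Validator approvals needed per submission (default 2).
#' @param screen_outliers Run the outlier-removal step (default TRUE).
#' @param smote Balance each shard with SMOTE when its minority class
#'   exceeds `pconfig$smote_k` (default TRUE).
#' @param val_frac,test_frac,pool_frac Shared-set fractions.
#' @param seed Integer master seed; every later round derives its seeds
#'   from it.
#' @return An object of class `federation_state`.
#' @export
init_federation <- function(cohort, roster = default_roster(), skew = 1,
                            dconfig = distill_config(),
                            pconfig = preprocess_config(),
                            n_validators = 3L, quorum = 2L,
                            screen_outliers = TRUE, smote = TRUE,
                            val_frac = 0.15, test_frac = 0.15,
                            pool_frac = 0.20, seed = 1L) {
  validate_cohort(cohort)
  validate_roster(roster)

  if (screen_outliers) {
    cohort <- remove_outliers(cohort, pconfig)$cohort
  }
  partition <- partition_non_iid(
    cohort, roster, skew = skew,
    val_frac = val_frac, test_frac = test_frac, pool_frac = pool_frac,
    seed = seed
  )
  train_rows <- sort(unlist(partition$shards, use.names = FALSE))
  binned <- engineer_bins(cohort, pconfig, fit_rows = train_rows)
  feats <- as.matrix(binned[c(cohort_feature_names(), "glucose_bin", "insulin_bin")])
  zs <- zscore_fit(feats, fit_rows = train_rows)
  X <- zs$transformed
  y <- cohort$outcome

  # Per-shard SMOTE after splitting, so shared sets never see synthetic rows.
  shard_data <- lapply(seq_len(nrow(roster)), function(i) {
    idx <- partition$shards[[as.character(roster$id[i])]]
    sx <- X[idx, , drop = FALSE]
    sy <- y[idx]
    counts <- tabulate(sy + 1L, 2L)
    if (smote && counts[1] != counts[2] && min(counts) > pconfig$smote_k) {
      smote_balance(sx, sy, k = pconfig$smote_k, seed = seed + 7L * i)
    } else {
      list(features = sx, labels = sy)
    }
  })

  ledger <- ledger_new(quorum = quorum)
  for (i in seq_len(nrow(roster))) {
    ledger <- register_client(ledger, participant_address(roster$id[i]),
                              "model_provider")
  }
  validators <- sprintf("0xV%02d", seq_len(n_validators))
  for (v in validators) ledger <- register_client(ledger, v, "validator")
  ledger <- register_client(ledger, "0xAGG", "aggregator")

  state <- structure(
    list(
      X = X, y = y, partition = partition, roster = roster,
      shard_data = shard_data, ledger = ledger, validators = validators,
      dconfig = dconfig, pconfig = pconfig,
      moments = list(center = zs$center, scale = zs$scale),
      pseudo = list(features = NULL, labels = NULL, indices = integer(0)),
      models = vector("list", nrow(roster)),
      rounds = list(), seed = as.integer(seed)
    ),
    class = "federation_state"
  )
  run_round0(state)
}

participant_address <- function(id) sprintf("0xP%02d", id)

# Round 0: shard-only training and evaluation; no exchange, no aggregation.
run_round0 <- function(state) {
  roster <- state$roster
  test_idx <- state$partition$test
  val_idx <- state$partition$validation
  metrics <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    model <- build_model(roster[i, ])
    model <- train_local(
      model, state$shard_data[[i]]$features, state$shard_data[[i]]$labels,
      seed = round_seed(state$seed, 0L, i)
    )
    val_probs <- predict_soft(model, state$X[val_idx, , drop = FALSE])
    model$last_validation_accuracy <-
      evaluate_predictions(val_probs, state$y[val_idx])$accuracy
    test_probs <- predict_soft(model, state$X[test_idx, , drop = FALSE])
    metrics[[i]] <- dplyr::mutate(
      evaluate_predictions(test_probs, state$y[test_idx]),
      round = 0L, participant = roster$id[i], model_kind = roster$model_kind[i],
      validation_accuracy = model$last_validation_accuracy,
      .before = 1
    )
    state$models[[i]] <- model
  }
  state$rounds[["0"]] <- list(
    round = 0L,
    weights = tibble::tibble(
      participant = roster$id, weight = roster$static_weight,
      source_accuracy = NA_real_
    ),
    metrics = dplyr::bind_rows(metrics),
    ensemble_metrics = NULL,
    accepted_pseudo_count = 0L
  )
  state
}

round_seed <- function(base, t, i) as.integer(base + 131L * t + i)

#' Execute one federated round
#'
#' Runs the full per-round chain: local retraining on shard plus current
#' pseudo-labels; soft-label prediction on the shared unlabeled pool;
#' temperature scaling; ledger-gated submission (identity, role, round,
#' timestamp, declared-accuracy checks, then quorum approval by the
#' validators); accuracy-proportional weights from the shared-validation
#' accuracies of the quorum-approved submissions, clipped at the weight
#' cap; weighted soft-vote aggregation; confidence filtering at tau; and
#' pseudo-label replacement for the next round. Participants and the
#' weighted ensemble are then evaluated on the shared test set.
#'
#' @param state A `federation_state` from [init_federation()].
#' @param t Round number (>= 1).
#' @return The updated state, with `state$rounds[[as.character(t)]]`
#'   holding the round record.
#' @export
run_round <- function(state, t) {
  stopifnot(inherits(state, "federation_state"), t >= 1)
  roster <- state$roster
  n_part <- nrow(roster)
  pool_idx <- state$partition$unlabeled_pool
  val_idx <- state$partition$validation
  test_idx <- state$partition$test
  dcfg <- state$dconfig

  state$ledger <- ledger_advance_round(state$ledger, t)

  scaled <- vector("list", n_part)
  test_scaled <- vector("list", n_part)
  accuracies <- numeric(n_part)
  tx_index <- rep(NA_integer_, n_part)

  for (i in seq_len(n_part)) {
    model <- train_local(
      state$models[[i]],
      state$shard_data[[i]]$features, state$shard_data[[i]]$labels,
      state$pseudo$features, state$pseudo$labels,
      seed = round_seed(state$seed, t, i)
    )
    val_probs <- predict_soft(model, state$X[val_idx, , drop = FALSE])
    acc <- evaluate_predictions(val_probs, state$y[val_idx])$accuracy
    model$last_validation_accuracy <- acc
    accuracies[i] <- acc
    pool_probs <- predict_soft(model, state$X[pool_idx, , drop = FALSE])
    scaled[[i]] <- temperature_scale(pool_probs, dcfg$temperature, dcfg$epsilon)
    test_scaled[[i]] <- temperature_scale(
      predict_soft(model, state$X[test_idx, , drop = FALSE]),
      dcfg$temperature, dcfg$epsilon
    )

    meta <- submission_metadata(
      sender = participant_address(roster$id[i]), round = t,
      declared_accuracy = acc, payload = scaled[[i]]
    )
    state$ledger <- submit_model_update(state$ledger, meta,
                                        recomputed_accuracy = acc)
    rec <- last_record(state$ledger)
    if (rec$status == "accepted") {
      tx_index[i] <- rec$index
      for (v in state$validators[seq_len(min(state$ledger$quorum,
                                             length(state$validators)))]) {
        state$ledger <- validator_approve(state$ledger, rec$index, v)
      }
    }
    state$models[[i]] <- model
  }

  eligible <- which(
    !is.na(tx_index) &
      vapply(tx_index, function(ix) {
        !is.na(ix) && submission_eligible(state$ledger, ix)
      }, logical(1))
  )
  if (length(eligible) == 0) {
    stop("round ", t, " aborted: no submission passed RBAC checks and quorum approval")
  }

  # a cap below 1/N is infeasible once submissions drop out; clamp to 1/N
  cap_eff <- max(dcfg$weight_cap, 1 / length(eligible))
  w <- clip_weights(compute_weights(accuracies[eligible]), cap_eff)
  global_pool <- aggregate_soft(scaled[eligible], w)
  filt <- filter_confident(global_pool, dcfg$tau)

  state$pseudo <- list(   # replace, never accumulate
    features = state$X[pool_idx[filt$indices], , drop = FALSE],
    labels = filt$labels[filt$indices],
    indices = pool_idx[filt$indices]
  )

  metrics <- purrr::map_dfr(seq_len(n_part), function(i) {
    # scaling is monotone per row, so argmax metrics match the raw scores
    dplyr::mutate(
      evaluate_predictions(test_scaled[[i]], state$y[test_idx]),
      round = t, participant = roster$id[i], model_kind = roster$model_kind[i],
      validation_accuracy = accuracies[i],
      .before = 1
    )
  })
  global_test <- aggregate_soft(test_scaled[eligible], w)
  ensemble_metrics <- dplyr::mutate(
    evaluate_predictions(global_test, state$y[test_idx]),
    round = t, .before = 1
  )
  state$ledger <- aggregate_mark(state$ledger, "0xAGG")

  state$rounds[[as.character(t)]] <- list(
    round = t,
    weights = tibble::tibble(
      participant = roster$id[eligible], weight = w,
      source_accuracy = accuracies[eligible]
    ),
    metrics = metrics,
    ensemble_metrics = ensemble_metrics,
    global_test_probs = global_test,
    accepted_pseudo_count = length(filt$indices)
  )
  state
}

#' Run the full multi-round federation
#'
#' Convenience driver: [init_federation()] followed by `rounds` calls to
#' [run_round()], returning a `federation_result` that carries the
#' per-round participant metrics, ensemble metrics, weight history,
#' pseudo-label acceptance counts, the final ensemble test predictions
#' and the complete trust ledger.
#'
#' @inheritParams init_federation
#' @param rounds Number of communication rounds after round 0
#'   (default 15).
#' @return An object of class `federation_result`. Use [tidy()] for the
#'   per-round metrics tibble, [glance()] for the per-participant
#'   summary, and [ggplot2::autoplot()] for accuracy trajectories.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(600, seed = 3)
#' res <- run_federation(cohort, rounds = 3, seed = 3)
#' glance(res)
#' }
#' @export
run_federation <- function(cohort, roster = default_roster(), rounds = 15L,
                           skew = 1, dconfig = distill_config(),
                           pconfig = preprocess_config(),
                           n_validators = 3L, quorum = 2L,
                           screen_outliers = TRUE, smote = TRUE,
                           val_frac = 0.15, test_frac = 0.15,
                           pool_frac = 0.20, seed = 1L) {
  state <- init_federation(
    cohort, roster, skew = skew, dconfig = dconfig, pconfig = pconfig,
    n_validators = n_validators, quorum = quorum,
    screen_outliers = screen_outliers, smote = smote,
    val_frac = val_frac, test_frac = test_frac, pool_frac = pool_frac,
    seed = seed
  )
  for (t in seq_len(rounds)) state <- run_round(state, t)

  records <- state$rounds
  metrics <- dplyr::bind_rows(lapply(records, `[[`, "metrics"))
  ensemble_metrics <- dplyr::bind_rows(lapply(records, `[[`, "ensemble_metrics"))
  weights_history <- dplyr::bind_rows(lapply(records, function(r) {
    dplyr::mutate(r$weights, round = r$round, .before = 1)
  }))
  accepted <- tibble::tibble(
    round = vapply(records, `[[`, integer(1), "round"),
    accepted_pseudo_count = vapply(records, `[[`, integer(1),
                                   "accepted_pseudo_count")
  )
  last <- records[[as.character(rounds)]]
  structure(
    list(
      metrics = metrics,
      ensemble_metrics = ensemble_metrics,
      weights_history = weights_history,
      accepted_pseudo = accepted,
      final_test_probs = if (rounds >= 1) last$global_test_probs else NULL,
      test_truth = state$y[state$partition$test],
      ledger = state$ledger,
      roster = state$roster,
      partition = state$partition,
      rounds = rounds,
      seed = state$seed,
      config = list(
        skew = skew, dconfig = unclass(dconfig), pconfig = unclass(pconfig),
        n_validators = n_validators, quorum = quorum,
        screen_outliers = screen_outliers, smote = smote,
        val_frac = val_frac, test_frac = test_frac, pool_frac = pool_frac
      )
    ),
    class = "federation_result"
  )
}

#' @export
print.federation_result <- function(x, ...) {
  cat(sprintf(
    "<federation_result> %d participants, %d rounds, seed %d\n",
    nrow(x$roster), x$rounds, x$seed
  ))
  if (!is.null(x$final_test_probs)) {
    fin <- x$ensemble_metrics[x$ensemble_metrics$round == x$rounds, ]
    cat(sprintf(
      "  final ensemble test accuracy %.3f (precision %.3f, recall %.3f, f1 %.3f)\n",
      fin$accuracy, fin$precision, fin$recall, fin$f1
    ))
  }
  cat(sprintf("  ledger: %d tx, rejection rate %.2f%%\n",
              nrow(x$ledger$log), audit_report(x$ledger)$rejection_rate))
  invisible(x)
}

#' Write all federation artifacts to a run directory
#'
#' Emits `metrics.csv` (round x participant metrics), `ensemble_metrics.csv`,
#' `weights.jsonl` (one weight vector per round), `ledger.jsonl`,
#' `audit.json` and `manifest.json` (seed plus a SHA-256 hash of the run
#' configuration). Identical `(config, seed)` runs produce byte-identical
#' files.
#'
#' @param result A `federation_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_federation_outputs <- function(result, dir) {
  stopifnot(inherits(result, "federation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    result$metrics[c("round", "participant", "model_kind", "accuracy",
                     "precision", "recall", "f1")],
    file.path(dir, "metrics.csv")
  )
  readr::write_csv(result$ensemble_metrics[c("round", "accuracy", "precision",
                                             "recall", "f1")],
                   file.path(dir, "ensemble_metrics.csv"))
  wl <- split(result$weights_history, result$weights_history$round)
  writeLines(
    vapply(wl, function(d) {
      jsonlite::toJSON(as.list(d), auto_unbox = FALSE, digits = NA)
    }, character(1)),
    file.path(dir, "weights.jsonl")
  )
  write_ledger_log(result$ledger, file.path(dir, "ledger.jsonl"))
  audit <- audit_report(result$ledger)
  jsonlite::write_json(
    list(
      total = audit$total, valid = audit$valid, rejected = audit$rejected,
      rejected_by_reason = as.list(audit$rejected_by_reason),
      rejection_rate = audit$rejection_rate,
      valid_success_rate = audit$valid_success_rate
    ),
    file.path(dir, "audit.json"), auto_unbox = TRUE, digits = NA
  )
  cfg_json <- jsonlite::toJSON(result$config, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(
      seed = result$seed, rounds = result$rounds,
      config_sha256 = digest::digest(as.character(cfg_json), algo = "sha256",
                                     serialize = FALSE)
    ),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
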