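small_run <- function(seed = 5, rounds = 2, n = 500, effect = 1, skew = 1, ...) {
  cohort <- generate_cohort(n, 0.35, effect, seed = seed)
  suppressWarnings(run_federation(cohort, rounds = rounds, seed = seed,
                                  skew = skew, ...))
}

test_that("a federation run is deterministic down to its artifacts", {
  a <- small_run(seed = 5)
  b <- small_run(seed = 5)
  expect_equal(a$metrics, b$metrics, tolerance = 0)
  expect_equal(a$weights_history, b$weights_history, tolerance = 0)
  expect_identical(a$ledger$log, b$ledger$log)
  c <- small_run(seed = 6)
  expect_false(isTRUE(all.equal(a$metrics$accuracy, c$metrics$accuracy)))
})

test_that("round records satisfy their structural contracts", {
  res <- small_run(seed = 7, rounds = 3)
  expect_equal(nrow(res$metrics), 4 * 5)  # rounds 0..3 x 5 participants
  expect_true(all(res$metrics$accuracy >= 0 & res$metrics$accuracy <= 1))
  pool_size <- length(res$partition$unlabeled_pool)
  expect_true(all(res$accepted_pseudo$accepted_pseudo_count <= pool_size))
  # weights per round: sum 1, capped
  for (t in 1:3) {
    w <- res$weights_history$weight[res$weights_history$round == t]
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_lte(max(w), 0.5 + 1e-9)
  }
  # ledger saw one accepted submission per participant per round
  ups <- res$ledger$log[res$ledger$log$kind == "model_update", ]
  expect_equal(nrow(ups), 3 * 5)
  expect_true(all(ups$status == "accepted"))
})

test_that("a single-participant federation reduces to its own scaled soft labels", {
  roster <- default_roster()[1, ]
  roster$data_fraction <- 0.9
  roster$static_weight <- 1
  cohort <- generate_cohort(400, 0.35, 1, seed = 8)
  state <- suppressWarnings(init_federation(cohort, roster, seed = 8))
  state <- run_round(state, 1)
  pool <- state$partition$unlabeled_pool
  own <- temperature_scale(
    predict_soft(state$models[[1]], state$X[pool, , drop = FALSE]), 2
  )
  filt <- filter_confident(own, 0.7)
  expect_identical(state$pseudo$indices, pool[filt$indices])
  expect_identical(state$pseudo$labels, filt$labels[filt$indices])
})

test_that("a round aborts when no submission can reach quorum", {
  cohort <- generate_cohort(400, 0.35, 1, seed = 9)
  # quorum larger than the validator set: nothing can become eligible
  state <- suppressWarnings(
    init_federation(cohort, seed = 9, n_validators = 1L, quorum = 3L)
  )
  expect_error(run_round(state, 1), "aborted")
})

test_that("per-participant accuracy SD matches recomputation from the trajectory", {
  res <- small_run(seed = 10, rounds = 4)
  g <- glance(res)
  for (pid in res$roster$id) {
    traj <- res$metrics$accuracy[res$metrics$participant == pid &
                                   res$metrics$round >= 1]
    expect_equal(g$sd_accuracy[g$participant == pid], sd(traj),
                 tolerance = 1e-12)
    expect_equal(g$mean_accuracy[g$participant == pid], mean(traj),
                 tolerance = 1e-12)
  }
})

test_that("zero-signal cohorts yield few first-round pseudo-labels and no drift", {
  res <- small_run(seed = 11, rounds = 3, n = 800, effect = 0, skew = 0)
  pool_size <- length(res$partition$unlabeled_pool)
  first <- res$accepted_pseudo$accepted_pseudo_count[
    res$accepted_pseudo$round == 1
  ]
  expect_lt(first / pool_size, 0.10)
  acc <- res$ensemble_metrics$accuracy
  expect_lt(abs(acc[length(acc)] - acc[1]), 0.15)
})

test_that("the ensemble is no worse than the weighted mean of its members", {
  # tolerance 0.06 ~ 2 SE of a shared-test accuracy estimate at this scale
  for (seed in 10:19) {
    res <- small_run(seed = seed, rounds = 2, n = 1200)
    for (t in 1:2) {
      w <- res$weights_history[res$weights_history$round == t, ]
      m <- res$metrics[res$metrics$round == t, ]
      member_mean <- sum(w$weight * m$accuracy[match(w$participant, m$participant)])
      ens <- res$ensemble_metrics$accuracy[res$ensemble_metrics$round == t]
      expect_gte(ens, member_mean - 0.06)
    }
  }
})

test_that("federation outputs round-trip to a run directory deterministically", {
  res <- small_run(seed = 14, rounds = 2, n = 400)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_federation_outputs(res, d1)
  write_federation_outputs(small_run(seed = 14, rounds = 2, n = 400), d2)
  for (f in c("metrics.csv", "ensemble_metrics.csv", "ledger.jsonl",
              "audit.json", "weights.jsonl", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  audit <- jsonlite::read_json(file.path(d1, "audit.json"))
  expect_equal(audit$valid_success_rate, 100)
})

test_that("tidiers and autoplot expose the result surfaces", {
  res <- small_run(seed = 15, rounds = 2, n = 400)
  td <- tidy(res)
  expect_true(all(c("round", "participant", "accuracy", "f1") %in% names(td)))
  g <- glance(res)
  expect_equal(nrow(g), 5)
  expect_true(all(c("initial_accuracy", "final_accuracy", "improvement")
                  %in% names(g)))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_pseudo_acceptance(res), "ggplot")
})
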