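valid_payload <- function(n = 4) random_prob_rows(n, seed = 1)

provider_ledger <- function(quorum = 2) {
  led <- ledger_new(quorum = quorum)
  led <- register_client(led, "0xP01", "model_provider")
  led <- register_client(led, "0xV01", "validator")
  led <- register_client(led, "0xV02", "validator")
  led <- register_client(led, "0xAGG", "aggregator")
  ledger_advance_round(led, 1)
}

submit_ok <- function(led, sender = "0xP01", acc = 0.8, round = 1, ts = NULL) {
  meta <- submission_metadata(sender, round, acc, valid_payload(), timestamp = ts)
  submit_model_update(led, meta, recomputed_accuracy = acc)
}

test_that("registration accepts fresh addresses and rejects duplicates and bad roles", {
  led <- ledger_new()
  led <- register_client(led, "0xA", "model_provider")
  expect_identical(last_record(led)$status, "accepted")
  led <- register_client(led, "0xA", "model_provider")
  expect_identical(last_record(led)$reason, "already registered")
  led <- register_client(led, "0xB", "admin")
  expect_identical(last_record(led)$reason, "invalid role")
  expect_false("0xB" %in% names(led$registered))
})

test_that("submission checks fire in the documented order", {
  led <- provider_ledger()

  bad <- submit_ok(led, sender = "0xNOBODY")
  expect_identical(last_record(bad)$reason, "Client not registered")

  bad <- submit_ok(led, sender = "0xV01")   # wrong role
  expect_identical(last_record(bad)$reason, "unauthorized role")

  bad <- submit_ok(led, round = 5)
  expect_identical(last_record(bad)$reason, "round mismatch")

  # malicious: declared accuracy far from the recomputed one
  meta <- submission_metadata("0xP01", 1, 0.99, valid_payload())
  bad <- submit_model_update(led, meta, recomputed_accuracy = 0.70)
  expect_identical(last_record(bad)$reason, "metadata mismatch")

  meta <- submission_metadata("0xP01", 1, 0.8, rbind(c(0.9, 0.3)))
  bad <- submit_model_update(bad, meta, recomputed_accuracy = 0.8)
  expect_identical(last_record(bad)$reason, "invalid payload")

  ok <- submit_ok(led)
  rec <- last_record(ok)
  expect_identical(rec$status, "accepted")
  expect_match(rec$payload_hash, "^[0-9a-f]{64}$")

  # replayed (non-monotone) timestamp from the same sender
  stale <- submit_ok(ok, ts = rec$timestamp)
  expect_identical(last_record(stale)$reason, "non-monotone timestamp")
})

test_that("payload digests are canonical and tamper-evident", {
  p <- valid_payload(6)
  expect_identical(payload_digest(p), payload_digest(p))
  tampered <- p
  tampered[3, 1] <- tampered[3, 1] + 1e-9
  expect_false(payload_digest(p) == payload_digest(tampered))
  expect_false(payload_digest(p) == payload_digest(t(p)))
})

test_that("quorum approval uses distinct-validator set semantics", {
  led <- provider_ledger(quorum = 2)
  led <- submit_ok(led)
  tx <- last_record(led)$index

  led <- validator_approve(led, tx, "0xV01")
  expect_false(submission_eligible(led, tx))
  led <- validator_approve(led, tx, "0xV01")   # same validator counts once
  expect_false(submission_eligible(led, tx))
  led <- validator_approve(led, tx, "0xV02")
  expect_true(submission_eligible(led, tx))

  # non-validator approval is recorded as rejected, never counted
  led2 <- provider_ledger(quorum = 1)
  led2 <- submit_ok(led2)
  tx2 <- last_record(led2)$index
  led2 <- validator_approve(led2, tx2, "0xAGG")
  expect_false(submission_eligible(led2, tx2))
  expect_false(led2$approvals$accepted[nrow(led2$approvals)])
})

test_that("audit counts conserve and an empty ledger reports zeros", {
  audit0 <- audit_report(ledger_new())
  expect_equal(audit0$total, 0L)
  expect_equal(audit0$rejection_rate, 0)
  expect_equal(audit0$valid_success_rate, 0)

  led <- provider_ledger()
  led <- submit_ok(led)
  led <- submit_ok(led, sender = "0xGHOST")
  led <- ledger_query(led, "0xGHOST")
  audit <- audit_report(led)
  expect_equal(audit$valid + audit$rejected, audit$total)
  expect_equal(sum(audit$rejected_by_reason), audit$rejected)
  expect_equal(audit$valid_success_rate, 100)
  td <- tidy(audit)
  expect_equal(sum(td$count), audit$total)
})

test_that("ledger logs replay byte-for-byte and reconstruct the audit", {
  build <- function() {
    led <- provider_ledger()
    led <- submit_ok(led)
    led <- assign_role(led, "0xP01", "superuser")
    led <- ledger_query(led, "0xEVE")
    led <- aggregate_mark(led, "0xAGG")
    led
  }
  a <- build()
  b <- build()
  pa <- withr::local_tempfile(fileext = ".jsonl")
  pb <- withr::local_tempfile(fileext = ".jsonl")
  write_ledger_log(a, pa)
  write_ledger_log(b, pb)
  expect_identical(readLines(pa), readLines(pb))

  rep <- replay_ledger(pa)
  expect_equal(rep$audit$total, nrow(a$log))
  expect_equal(rep$audit$rejected, sum(a$log$status == "rejected"))
  expect_equal(as.data.frame(rep$log), as.data.frame(a$log), tolerance = 1e-12)
})

test_that("fuzzed sequences never admit unauthorized or wrongly-roled updates", {
  set.seed(99)
  addresses <- sprintf("0x%02d", 1:12)
  for (run in 1:40) {
    led <- ledger_new(quorum = 2)
    shadow <- character(0)   # independently tracked address -> role
    n_ops <- sample(10:25, 1)
    for (op in seq_len(n_ops)) {
      kind <- sample(c("register", "submit", "query", "assign"), 1)
      addr <- sample(addresses, 1)
      if (kind == "register") {
        role <- sample(c("model_provider", "validator", "aggregator", "bogus"), 1)
        if (role != "bogus" && !addr %in% names(shadow)) shadow[addr] <- role
        led <- register_client(led, addr, role)
      } else if (kind == "submit") {
        acc <- runif(1)
        declared <- if (runif(1) < 0.7) acc else runif(1)
        was_provider <- addr %in% names(shadow) &&
          shadow[[addr]] == "model_provider"
        meta <- submission_metadata(addr, led$current_round, declared,
                                    valid_payload())
        led <- submit_model_update(led, meta, recomputed_accuracy = acc)
        # the critical invariant: no acceptance without the provider role
        if (!was_provider) {
          expect_identical(last_record(led)$status, "rejected")
        }
      } else if (kind == "query") {
        led <- ledger_query(led, addr)
      } else {
        role <- sample(c("model_provider", "bogus"), 1)
        if (role != "bogus" && addr %in% names(shadow)) shadow[addr] <- role
        led <- assign_role(led, addr, role)
      }
    }
    log <- led$log
    # log indices dense and strictly increasing
    expect_identical(log$index, seq_len(nrow(log)))
    expect_equal(sum(log$status == "accepted") + sum(log$status == "rejected"),
                 nrow(log))
    expect_true(all(log$reason != "" | log$status == "accepted"))
    expect_true(all(log$status != "rejected" | log$reason != ""))
  }
})
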