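#' Create an empty permissioned trust ledger
#'
#' An in-process simulator of the role-based-access-control coordination
#' layer: participants register under one of three roles
#' (`model_provider`, `validator`, `aggregator`), every action is
#' appended to an immutable transaction log with an accept/reject status
#' and reason, accepted soft-label submissions are SHA-256 hashed for
#' auditability, and a submission only becomes aggregation-eligible once
#' a quorum of distinct validators approves it.
#'
#' @param quorum Number of distinct validator approvals a submission
#'   needs (default 2).
#' @return An object of class `trust_ledger`.
#' @examples
#' led <- ledger_new()
#' led <- register_client(led, "0xA1", "model_provider")
#' last_record(led)
#' @export
ledger_new <- function(quorum = 2L) {
  stopifnot(quorum >= 1)
  structure(
    list(
      registered = character(0),           # named: address -> role
      validators = character(0),
      log = empty_ledger_log(),
      approvals = tibble::tibble(
        tx_index = integer(0), validator = character(0),
        accepted = logical(0), reason = character(0)
      ),
      current_round = 0L,
      quorum = as.integer(quorum),
      clock = 0L
    ),
    class = "trust_ledger"
  )
}

ledger_roles <- function() c("model_provider", "validator", "aggregator")

empty_ledger_log <- function() {
  tibble::tibble(
    index = integer(0), kind = character(0), sender = character(0),
    status = character(0), reason = character(0),
    payload_hash = character(0), round = integer(0),
    declared_accuracy = numeric(0), timestamp = integer(0)
  )
}

# Append one immutable record; the monotone clock stamps it.
ledger_append <- function(ledger, kind, sender, status, reason = "",
                          payload_hash = "", round = ledger$current_round,
                          declared_accuracy = NA_real_,
                          timestamp = NULL) {
  ledger$clock <- ledger$clock + 1L
  rec <- tibble::tibble(
    index = nrow(ledger$log) + 1L,
    kind = kind, sender = sender, status = status, reason = reason,
    payload_hash = payload_hash, round = as.integer(round),
    declared_accuracy = declared_accuracy,
    timestamp = as.integer(timestamp %||% ledger$clock)
  )
  ledger$log <- dplyr::bind_rows(ledger$log, rec)
  ledger
}

#' Most recent transaction record
#'
#' @param ledger A `trust_ledger`.
#' @return One-row tibble: the last appended record.
#' @export
last_record <- function(ledger) {
  stopifnot(inherits(ledger, "trust_ledger"))
  ledger$log[nrow(ledger$log), , drop = FALSE]
}

#' Register a client address under a role
#'
#' A fresh address with a valid role is accepted and recorded; an
#' unknown role or a duplicate registration is recorded as a rejected
#' transaction (all failures are rejections, never errors).
#'
#' @param ledger A `trust_ledger`.
#' @param address Client address string.
#' @param role One of `model_provider`, `validator`, `aggregator`.
#' @return The updated ledger.
#' @export
register_client <- function(ledger, address, role) {
  stopifnot(inherits(ledger, "trust_ledger"))
  if (!role %in% ledger_roles()) {
    return(ledger_append(ledger, "register", address, "rejected", "invalid role"))
  }
  if (address %in% names(ledger$registered)) {
    return(ledger_append(ledger, "register", address, "rejected", "already registered"))
  }
  ledger$registered[address] <- role
  if (role == "validator") ledger$validators <- union(ledger$validators, address)
  ledger_append(ledger, "register", address, "accepted")
}

#' Reassign the role of a registered client
#'
#' Rejected (and logged) when the address is unregistered or the role is
#' not in the role set — the latter is the "invalid role update"
#' category of the integrity audit.
#'
#' @inheritParams register_client
#' @return The updated ledger.
#' @export
assign_role <- function(ledger, address, role) {
  stopifnot(inherits(ledger, "trust_ledger"))
  if (!role %in% ledger_roles()) {
    return(ledger_append(ledger, "assign_role", address, "rejected", "invalid role"))
  }
  if (!address %in% names(ledger$registered)) {
    return(ledger_append(ledger, "assign_role", address, "rejected", "Client not registered"))
  }
  old <- ledger$registered[[address]]
  ledger$registered[address] <- role
  if (role == "validator") {
    ledger$validators <- union(ledger$validators, address)
  } else if (old == "validator") {
    ledger$validators <- setdiff(ledger$validators, address)
  }
  ledger_append(ledger, "assign_role", address, "accepted")
}

#' Query the ledger as a client
#'
#' Reads from unregistered addresses are rejected and logged as
#' unauthorized queries; registered clients get an accepted query record.
#'
#' @param ledger A `trust_ledger`.
#' @param address Querying address.
#' @return The updated ledger.
#' @export
ledger_query <- function(ledger, address) {
  stopifnot(inherits(ledger, "trust_ledger"))
  if (!address %in% names(ledger$registered)) {
    return(ledger_append(ledger, "query", address, "rejected", "unauthorized query"))
  }
  ledger_append(ledger, "query", address, "accepted")
}

#' Build submission metadata for a soft-label update
#'
#' @param sender Submitting address.
#' @param round Federated round the submission targets.
#' @param declared_accuracy Validation accuracy the sender claims.
#' @param payload Soft-label probability matrix being submitted.
#' @param timestamp Optional monotone counter value; defaults to the
#'   ledger clock at submission time.
#' @return A list of class `submission_metadata`.
#' @export
submission_metadata <- function(sender, round, declared_accuracy, payload,
                                timestamp = NULL) {
  structure(
    list(
      sender = sender, round = as.integer(round),
      declared_accuracy = declared_accuracy,
      payload = as.matrix(payload), timestamp = timestamp
    ),
    class = "submission_metadata"
  )
}

#' Submit a soft-label model update through the RBAC checks
#'
#' The submission is accepted only if every check passes, in this fixed
#' order (the reason recorded on rejection is the first failing check):
#' sender registered; sender role is `model_provider`; declared round
#' equals the ledger's current round; timestamp exceeds the sender's
#' last accepted submission; declared accuracy matches the accuracy the
#' aggregator recomputed on the shared validation set within
#' `tolerance`; payload rows are valid probability distributions. On
#' acceptance the SHA-256 digest of the canonical payload bytes is
#' logged.
#'
#' @param ledger A `trust_ledger`.
#' @param meta A [submission_metadata()].
#' @param recomputed_accuracy Accuracy the aggregator measured for this
#'   sender on the shared validation set.
#' @param tolerance Allowed |declared - recomputed| gap (default 1e-6).
#' @return The updated ledger.
#' @export
submit_model_update <- function(ledger, meta, recomputed_accuracy,
                                tolerance = 1e-6) {
  stopifnot(inherits(ledger, "trust_ledger"), inherits(meta, "submission_metadata"))
  ts <- as.integer(meta$timestamp %||% (ledger$clock + 1L))
  reject <- function(reason) {
    ledger_append(
      ledger, "model_update", meta$sender, "rejected", reason,
      round = meta$round, declared_accuracy = meta$declared_accuracy,
      timestamp = ts
    )
  }
  if (!meta$sender %in% names(ledger$registered)) {
    return(reject("Client not registered"))
  }
  if (ledger$registered[[meta$sender]] != "model_provider") {
    return(reject("unauthorized role"))
  }
  if (meta$round != ledger$current_round) {
    return(reject("round mismatch"))
  }
  prev <- ledger$log$timestamp[
    ledger$log$sender == meta$sender &
      ledger$log$kind == "model_update" &
      ledger$log$status == "accepted"
  ]
  if (length(prev) > 0 && ts <= max(prev)) {
    return(reject("non-monotone timestamp"))
  }
  if (!is.finite(meta$declared_accuracy) ||
      abs(meta$declared_accuracy - recomputed_accuracy) > tolerance) {
    return(reject("metadata mismatch"))
  }
  pl <- meta$payload
  if (anyNA(pl) || any(pl < 0) || any(abs(rowSums(pl) - 1) > 1e-6)) {
    return(reject("invalid payload"))
  }
  ledger_append(
    ledger, "model_update", meta$sender, "accepted",
    payload_hash = payload_digest(pl),
    round = meta$round, declared_accuracy = meta$declared_accuracy,
    timestamp = ts
  )
}

#' SHA-256 digest of a soft-label payload
#'
#' Hashes a canonical byte serialization (dimensions plus row-major
#' entries printed with fixed scientific formatting), so digests are
#' platform-stable and any single-entry tampering changes the digest.
#'
#' @param payload Numeric probability matrix.
#' @return 64-character lowercase hex digest.
#' @export
payload_digest <- function(payload) {
  payload <- as.matrix(payload)
  canonical <- paste(
    c(dim(payload), sprintf("%.12e", as.vector(t(payload)))),
    collapse = ","
  )
  digest::digest(canonical, algo = "sha256", serialize = FALSE)
}

#' Record a validator's approval of an accepted submission
#'
#' Approvals are idempotent per validator (a validator approving twice
#' counts once) and tracked on a separate approval trail, not in the
#' transaction log. Approvals from non-validators, or of transactions
#' that are not accepted model updates, are recorded as rejected
#' approval attempts.
#'
#' @param ledger A `trust_ledger`.
#' @param tx_index Index of an accepted `model_update` record.
#' @param validator Approving address.
#' @return The updated ledger.
#' @export
validator_approve <- function(ledger, tx_index, validator) {
  stopifnot(inherits(ledger, "trust_ledger"))
  note <- function(ok, reason = "") {
    ledger$approvals <- dplyr::bind_rows(
      ledger$approvals,
      tibble::tibble(
        tx_index = as.integer(tx_index), validator = validator,
        accepted = ok, reason = reason
      )
    )
    ledger
  }
  if (!validator %in% ledger$validators) {
    return(note(FALSE, "approver is not a validator"))
  }
  rec <- ledger$log[ledger$log$index == tx_index, , drop = FALSE]
  if (nrow(rec) != 1 || rec$kind != "model_update" || rec$status != "accepted") {
    return(note(FALSE, "target is not an accepted model update"))
  }
  already <- ledger$approvals$accepted &
    ledger$approvals$tx_index == tx_index &
    ledger$approvals$validator == validator
  if (any(already)) {
    return(ledger)  # idempotent: counts once
  }
  note(TRUE)
}

#' Is a submission aggregation-eligible?
#'
#' @param ledger A `trust_ledger`.
#' @param tx_index Transaction index of an accepted model update.
#' @return `TRUE` when distinct validator approvals reach the quorum.
#' @export
submission_eligible <- function(ledger, tx_index) {
  ok <- ledger$approvals$accepted & ledger$approvals$tx_index == tx_index
  length(unique(ledger$approvals$validator[ok])) >= ledger$quorum
}

#' Mark an aggregation event on the ledger
#'
#' @param ledger A `trust_ledger`.
#' @param aggregator Address of the aggregator node.
#' @return The updated ledger (rejected when the sender does not hold
#'   the aggregator role).
#' @export
aggregate_mark <- function(ledger, aggregator) {
  stopifnot(inherits(ledger, "trust_ledger"))
  if (!aggregator %in% names(ledger$registered) ||
      ledger$registered[[aggregator]] != "aggregator") {
    return(ledger_append(ledger, "aggregate", aggregator, "rejected",
                         "unauthorized role"))
  }
  ledger_append(ledger, "aggregate", aggregator, "accepted")
}

#' Advance the ledger's current round
#'
#' @param ledger A `trust_ledger`.
#' @param round New round number; must not decrease.
#' @return The updated ledger.
#' @export
ledger_advance_round <- function(ledger, round) {
  stopifnot(inherits(ledger, "trust_ledger"))
  round <- as.integer(round)
  if (round < ledger$current_round) stop("round number cannot decrease")
  ledger$current_round <- round
  ledger
}

#' Transaction-integrity audit of a ledger log
#'
#' Counts are derived solely from the transaction log: totals, accepted
#' and rejected counts, rejected counts by reason, the rejection rate as
#' a percentage rounded to two decimals, and the success rate among
#' accepted transactions (100% by construction — an accepted record
#' never fails afterwards). An empty log yields the all-zero report.
#'
#' @param ledger A `trust_ledger`, or a log tibble read back with
#'   [read_ledger_log()].
#' @return A list of class `ledger_audit`.
#' @examples
#' audit_report(ledger_new())
#' @export
audit_report <- function(ledger) {
  log <- if (inherits(ledger, "trust_ledger")) ledger$log else ledger
  total <- nrow(log)
  if (total == 0) {
    return(structure(
      list(
        total = 0L, valid = 0L, rejected = 0L,
        rejected_by_reason = integer(0),
        rejection_rate = 0, valid_success_rate = 0
      ),
      class = "ledger_audit"
    ))
  }
  valid <- sum(log$status == "accepted")
  rejected <- total - valid
  by_reason <- table(log$reason[log$status == "rejected"])
  structure(
    list(
      total = total, valid = valid, rejected = rejected,
      rejected_by_reason = stats::setNames(as.integer(by_reason), names(by_reason)),
      rejection_rate = round(100 * rejected / total, 2),
      valid_success_rate = if (valid > 0) 100 else 0
    ),
    class = "ledger_audit"
  )
}

#' @export
print.ledger_audit <- function(x, ...) {
  cat("<ledger_audit>\n")
  cat(sprintf("  total %d | valid %d | rejected %d (%.2f%%)\n",
              x$total, x$valid, x$rejected, x$rejection_rate))
  if (length(x$rejected_by_reason) > 0) {
    cat("  rejected by reason:\n")
    for (r in names(x$rejected_by_reason)) {
      cat(sprintf("    %-28s %d\n", r, x$rejected_by_reason[[r]]))
    }
  }
  cat(sprintf("  success rate among valid: %g%%\n", x$valid_success_rate))
  invisible(x)
}

#' @export
print.trust_ledger <- function(x, ...) {
  cat(sprintf(
    "<trust_ledger> %d registered (%d validators), quorum %d, round %d, %d tx\n",
    length(x$registered), length(x$validators), x$quorum,
    x$current_round, nrow(x$log)
  ))
  invisible(x)
}

#' Persist / reload / replay a ledger log
#'
#' The log is written as JSONL (one transaction record per line).
#' `replay_ledger()` reads a log file back and recomputes the audit from
#' the records alone, so an auditor never needs the live ledger object.
#'
#' @param ledger A `trust_ledger`.
#' @param path JSONL file path.
#' @return `write_ledger_log()` the ledger invisibly; `read_ledger_log()`
#'   the log tibble; `replay_ledger()` a list with `log` and `audit`.
#' @export
write_ledger_log <- function(ledger, path) {
  stopifnot(inherits(ledger, "trust_ledger"))
  lines <- vapply(
    seq_len(nrow(ledger$log)),
    function(i) {
      jsonlite::toJSON(as.list(ledger$log[i, ]), auto_unbox = TRUE,
                       digits = NA, na = "null")
    },
    character(1)
  )
  writeLines(lines, path)
  invisible(ledger)
}

#' @rdname write_ledger_log
#' @export
read_ledger_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_ledger_log())
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec$declared_accuracy <- rec$declared_accuracy %||% NA_real_
    tibble::as_tibble(rec)
  })
  out <- dplyr::bind_rows(rows)
  out$index <- as.integer(out$index)
  out$round <- as.integer(out$round)
  out$timestamp <- as.integer(out$timestamp)
  out
}

#' @rdname write_ledger_log
#' @export
replay_ledger <- function(path) {
  log <- read_ledger_log(path)
  list(log = log, audit = audit_report(log))
}
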