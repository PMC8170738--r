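#' Register a new warning rule
#'
#' Newly added rules always enter the lifecycle as `pending_verification`:
#' they participate in automatic warning (their outcomes are shown, and a
#' purple block reminds staff to judge them) but cannot contribute to a
#' green auto-releasable state until a human confirms they execute as
#' intended. Registration is atomic — invalid parameters store nothing.
#'
#' @param session A [lab_session()].
#' @param rule_id Zero-padded 6-digit rule identifier (e.g. `"002009"`),
#'   unique within the session.
#' @param analyte_code Analyte the rule guards.
#' @param category Rule category, one of [rule_categories()].
#' @param params Category-specific parameters; validated with
#'   [validate_rule_params()].
#' @param scope Optional list restricting the rule to
#'   `detection_systems` and/or `specimen_types`.
#' @param now Registration timestamp (defaults to the wall clock).
#' @return The updated session.
#' @export
#' @examples
#' s <- lab_session() |>
#'   register_rule("002009", "CRP", "limit_range",
#'                 list(intercept_at_or_above = 5, units = "mg/l"))
#' rules(s)$status
register_rule <- function(session, rule_id, analyte_code, category,
                          params = list(), scope = NULL, now = Sys.time()) {
  stopifnot(inherits(session, "lab_session"))
  if (!is_scalar_chr(rule_id) || !grepl("^[0-9]{6}$", rule_id)) {
    abort("rule_id must be a zero-padded 6-digit string", class = "av_bad_input")
  }
  if (!is.null(session$rules[[rule_id]])) {
    abort(paste0("duplicate rule id: ", rule_id), class = "av_duplicate_rule")
  }
  params <- validate_rule_params(category, params)
  if (!is.null(scope)) {
    extra <- setdiff(names(scope), c("detection_systems", "specimen_types"))
    if (length(extra)) {
      abort(paste0("unknown scope field(s): ", paste(extra, collapse = ", ")),
            class = "av_bad_input")
    }
  }
  now <- av_time(now)
  session$rules[[rule_id]] <- list(
    id = rule_id, analyte_code = analyte_code, category = category,
    params = params, scope = scope, status = "pending_verification",
    created_at = now, status_changed_at = now,
    consistent_count = 0L, had_error = FALSE, failure_class = NULL
  )
  session$by_analyte[[analyte_code]] <-
    c(session$by_analyte[[analyte_code]], rule_id)
  append_audit(session, "rule_registered",
               list(rule_id = rule_id, analyte_code = analyte_code,
                    category = category),
               timestamp = now)
}

set_rule_status <- function(session, rule_id, status, now,
                            failure_class = NULL) {
  session$rules[[rule_id]]$status <- status
  session$rules[[rule_id]]$status_changed_at <- av_time(now)
  if (!is.null(failure_class)) {
    session$rules[[rule_id]]$failure_class <- failure_class
  }
  session
}

failure_classes <- c("human_error", "specific_warning_target",
                     "algorithm_code_error", "software_compatibility",
                     "expired")

#' Record a human judgment about a pending rule
#'
#' The correctness-verification touchpoint: having seen a pending rule
#' execute on a concrete report, staff record whether the machine's
#' behaviour matched their own judgment. A `consistent` judgment counts
#' toward verification (one confirmation flips the status by default); a
#' `system_error` judgment deletes the rule immediately — a rule that has
#' ever failed can never be converted to verified, and `deleted` is
#' terminal. At most one judgment is accepted per (rule, report) pair, so
#' one specimen can never certify a rule twice.
#'
#' @param session A [lab_session()].
#' @param rule_id Rule being judged; must be `pending_verification`.
#' @param barcode Report on which the rule's execution was observed.
#' @param judgment `"consistent"` or `"system_error"`.
#' @param failure_class Optional cause taxonomy for `system_error`
#'   judgments: one of `"human_error"`, `"specific_warning_target"`,
#'   `"algorithm_code_error"`, `"software_compatibility"`.
#' @param note Optional free-text note.
#' @param now Judgment timestamp.
#' @return The updated session.
#' @export
record_judgment <- function(session, rule_id, barcode, judgment,
                            failure_class = NULL, note = NULL,
                            now = Sys.time()) {
  stopifnot(inherits(session, "lab_session"))
  rule <- session$rules[[rule_id]]
  if (is.null(rule)) {
    abort(paste0("no such rule: ", rule_id), class = "av_no_such_rule")
  }
  if (rule$status != "pending_verification") {
    abort(paste0("rule ", rule_id, " is ", rule$status,
                 "; judgments apply only to pending rules"),
          class = "av_bad_transition")
  }
  if (!judgment %in% c("consistent", "system_error")) {
    abort("judgment must be 'consistent' or 'system_error'",
          class = "av_bad_input")
  }
  key <- paste0(rule_id, "|", barcode)
  if (key %in% session$judgment_keys) {
    abort(paste0("judgment already recorded for rule ", rule_id,
                 " on report ", barcode),
          class = "av_duplicate_judgment")
  }
  if (!is.null(failure_class) && !failure_class %in% failure_classes) {
    abort(paste0("unknown failure class: ", failure_class),
          class = "av_bad_input")
  }
  now <- av_time(now)
  session$judgment_keys <- c(session$judgment_keys, key)
  session <- append_audit(session, "judgment_recorded",
                          list(rule_id = rule_id, barcode = barcode,
                               judgment = judgment,
                               failure_class = failure_class,
                               note = note),
                          timestamp = now)
  if (judgment == "consistent") {
    n <- session$rules[[rule_id]]$consistent_count + 1L
    session$rules[[rule_id]]$consistent_count <- n
    if (n >= session$config$confirmations_required &&
        !session$rules[[rule_id]]$had_error) {
      session <- set_rule_status(session, rule_id, "verified", now)
      session <- append_audit(session, "rule_verified",
                              list(rule_id = rule_id), timestamp = now)
    }
  } else {
    session$rules[[rule_id]]$had_error <- TRUE
    session <- set_rule_status(session, rule_id, "deleted", now, failure_class)
    session <- append_audit(session, "rule_deleted",
                            list(rule_id = rule_id, cause = "system_error",
                                 failure_class = failure_class),
                            timestamp = now)
  }
  session
}

#' Auto-delete pending rules past the verification window
#'
#' A rule that fails to complete correctness verification within the
#' configured window (default 10 days) is deleted automatically — an
#' unverified rule must never linger in the system. The boundary is
#' strict: a rule pending exactly `expiry_days` is retained. The call is
#' idempotent at a fixed `now`.
#'
#' @param session A [lab_session()].
#' @param now Clock time of the sweep.
#' @return The updated session; ids deleted in this sweep are attached as
#'   attribute `"expired_ids"` and recorded in the audit log.
#' @export
expire_pending <- function(session, now = Sys.time()) {
  stopifnot(inherits(session, "lab_session"))
  now <- av_time(now)
  limit <- session$config$expiry_days * 86400
  expired <- character()
  for (id in names(session$rules)) {
    rule <- session$rules[[id]]
    if (rule$status != "pending_verification") next
    if (as.numeric(now) - as.numeric(rule$created_at) > limit) {
      session <- set_rule_status(session, id, "deleted", now, "expired")
      session <- append_audit(session, "rule_deleted",
                              list(rule_id = id, cause = "expired",
                                   failure_class = "expired"),
                              timestamp = now)
      expired <- c(expired, id)
    }
  }
  attr(session, "expired_ids") <- expired
  session
}

#' Rules are immutable: modification always fails
#'
#' Editing a rule in place would silently invalidate the human judgments
#' already recorded against it, so it is forbidden at the API level. The
#' supported (and audited) workflow is delete-then-register a new rule id.
#'
#' @param session A [lab_session()].
#' @param rule_id Rule id.
#' @param ... Ignored; present so mistaken call sites fail loudly rather
#'   than by arity.
#' @return Never returns.
#' @export
modify_rule <- function(session, rule_id, ...) {
  abort(paste0("rules are immutable; delete rule ", rule_id,
               " and register a replacement instead"),
        class = "av_modification_forbidden")
}

#' Has an analyte completed correctness verification?
#'
#' Integrity validation of an analyte ("project") may begin only after
#' every one of its non-deleted rules is verified. An analyte whose rules
#' are all deleted (or that never had any) has nothing to validate and is
#' an error.
#'
#' @param session A [lab_session()].
#' @param analyte_code Analyte ("project") code.
#' @return Logical scalar.
#' @export
is_project_verified <- function(session, analyte_code) {
  stopifnot(inherits(session, "lab_session"))
  ids <- session$by_analyte[[analyte_code]]
  statuses <- map_chr(session$rules[ids] %||% list(), "status")
  live <- statuses[statuses != "deleted"]
  if (length(live) == 0) {
    abort(paste0("analyte ", analyte_code, " has no non-deleted rules"),
          class = "av_no_rules")
  }
  all(live == "verified")
}
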