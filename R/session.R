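#' Create a laboratory validation session
#'
#' A `lab_session` bundles everything the validation workflow mutates: the
#' analyte catalog, the rule set with lifecycle status, per-analyte
#' integrity counters, patient history, recorded dispositions and the
#' append-only audit log. All state-changing verbs
#' (`register_rule()`, `record_judgment()`, `record_release()`,
#' `process_report()`, ...) take a session first and return the updated
#' session, so a whole validation run reads as one pipe.
#'
#' @param catalog Optional analyte catalog tibble (see [default_catalog()]);
#'   columns `code`, `name`, `units`, `panel`.
#' @param history Optional patient history tibble with columns
#'   `patient_id`, `analyte_code`, `value`, `collection_time`.
#' @param master_switch Logical; the laboratory-wide automated-reporting
#'   switch. Off by default: automated release must be opted into.
#' @param expiry_days Days a rule may stay `pending_verification` before it
#'   is auto-deleted by [expire_pending()]. Default 10.
#' @param confirmations_required Consistent human judgments needed before a
#'   pending rule flips to `verified`. Default 1.
#' @return A `lab_session` object.
#' @export
#' @examples
#' s <- lab_session(master_switch = TRUE)
#' rules(s)
lab_session <- function(catalog = NULL, history = NULL, master_switch = FALSE,
                        expiry_days = 10, confirmations_required = 1) {
  if (!is_finite_num(expiry_days) || expiry_days < 1) {
    abort("expiry_days must be >= 1", class = "av_bad_input")
  }
  if (!is_finite_num(confirmations_required) || confirmations_required < 1) {
    abort("confirmations_required must be >= 1", class = "av_bad_input")
  }
  if (!is.null(history)) history <- as_history(history)
  structure(list(
    catalog = catalog,
    rules = list(),              # id -> rule record
    by_analyte = list(),         # analyte_code -> character vector of rule ids
    counters = list(),           # analyte_code -> counter record
    history = history,
    judgment_keys = character(), # "rule_id|barcode" uniqueness guard
    audit_events = vector("list", 64L),
    audit_n = 0L,
    dispositions = list(),
    config = list(master_switch = isTRUE(master_switch),
                  expiry_days = expiry_days,
                  confirmations_required = confirmations_required)
  ), class = "lab_session")
}

#' @export
print.lab_session <- function(x, ...) {
  st <- table(factor(map_chr(x$rules, "status"),
                     levels = c("pending_verification", "verified", "deleted")))
  cat("<lab_session>\n")
  cat("  rules:   ", length(x$rules),
      sprintf(" (%d pending, %d verified, %d deleted)\n",
              st[["pending_verification"]], st[["verified"]], st[["deleted"]]))
  cat("  counters:", length(x$counters), "\n")
  cat("  audit:   ", x$audit_n, "events\n")
  cat("  switch:  ", if (x$config$master_switch) "on" else "off", "\n")
  invisible(x)
}

as_history <- function(history) {
  h <- as.data.frame(history, stringsAsFactors = FALSE)
  need <- c("patient_id", "analyte_code", "value", "collection_time")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    abort(paste0("history lacks column(s): ", paste(miss, collapse = ", ")),
          class = "av_bad_input")
  }
  h$collection_time <- av_time(h$collection_time)
  h[order(h$patient_id, h$collection_time), need, drop = FALSE]
}

append_audit <- function(session, kind, payload, timestamp = NULL) {
  n <- session$audit_n + 1L
  if (n > length(session$audit_events)) {
    length(session$audit_events) <- 2L * length(session$audit_events)
  }
  session$audit_events[[n]] <- list(
    seq_no = n,
    timestamp = timestamp %||% Sys.time(),
    kind = kind,
    payload = payload
  )
  session$audit_n <- n
  session
}

#' Rules table of a session
#'
#' @param session A [lab_session()].
#' @return Tibble with one row per registered rule: `rule_id`,
#'   `analyte_code`, `category`, `status`, `created_at`,
#'   `status_changed_at`, `failure_class`, and list-columns `params`,
#'   `scope`.
#' @export
rules <- function(session) {
  stopifnot(inherits(session, "lab_session"))
  rs <- unname(session$rules)
  if (!length(rs)) {
    return(tibble(rule_id = character(), analyte_code = character(),
                  category = character(), status = character(),
                  created_at = av_time(character()),
                  status_changed_at = av_time(character()),
                  failure_class = character(),
                  params = list(), scope = list()))
  }
  tibble(
    rule_id = map_chr(rs, "id"),
    analyte_code = map_chr(rs, "analyte_code"),
    category = map_chr(rs, "category"),
    status = map_chr(rs, "status"),
    created_at = av_time(map_dbl(rs, ~ as.numeric(.x$created_at))),
    status_changed_at = av_time(map_dbl(rs, ~ as.numeric(.x$status_changed_at))),
    failure_class = map_chr(rs, ~ .x$failure_class %||% NA_character_),
    params = map(rs, "params"),
    scope = map(rs, "scope")
  )
}

#' Integrity counters of a session
#'
#' @param session A [lab_session()].
#' @return Tibble with one row per analyte under integrity validation:
#'   `analyte_code`, `count`, `target`, `auto_enabled`, `n_cleared`.
#' @export
counters <- function(session) {
  stopifnot(inherits(session, "lab_session"))
  cs <- unname(session$counters)
  tibble(
    analyte_code = map_chr(cs, "analyte_code"),
    count = map_int(cs, "count"),
    target = map_int(cs, "target"),
    auto_enabled = map_lgl(cs, "auto_enabled"),
    n_cleared = map_int(cs, ~ length(.x$cleared_history))
  )
}

#' Audit log of a session
#'
#' The audit log is append-only: no operation in the package updates or
#' removes an event, and sequence numbers are gapless by construction.
#'
#' @param session A [lab_session()].
#' @return Tibble of events: `seq_no`, `timestamp`, `kind`, `payload`
#'   (list-column).
#' @export
audit_log <- function(session) {
  stopifnot(inherits(session, "lab_session"))
  evs <- session$audit_events[seq_len(session$audit_n)]
  tibble(
    seq_no = map_int(evs, "seq_no"),
    timestamp = av_time(map_dbl(evs, ~ as.numeric(.x$timestamp))),
    kind = map_chr(evs, "kind"),
    payload = map(evs, "payload")
  )
}

#' Report dispositions recorded in a session
#'
#' @param session A [lab_session()].
#' @return Tibble: `barcode`, `outcome`, `barcode_color`, `timestamp`.
#' @export
dispositions <- function(session) {
  stopifnot(inherits(session, "lab_session"))
  ds <- session$dispositions
  tibble(
    barcode = map_chr(ds, "barcode"),
    outcome = map_chr(ds, "outcome"),
    barcode_color = map_chr(ds, "barcode_color"),
    timestamp = av_time(map_dbl(ds, ~ as.numeric(.x$timestamp)))
  )
}

#' Turn the automated-reporting master switch on or off
#'
#' @param session A [lab_session()].
#' @param on Logical.
#' @return The updated session.
#' @export
set_master_switch <- function(session, on) {
  stopifnot(inherits(session, "lab_session"))
  session$config$master_switch <- isTRUE(on)
  session
}
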