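#' Dispose of a report through the autoverification flow
#'
#' Runs the automatic-warning stage and decides the report's fate:
#' a green report that is eligible for automated release (switch on, all
#' counters at target) is `auto_released`; a green report that is not yet
#' eligible goes to the manual queue (`manual_release_required`); a red or
#' purple report is `intercepted_for_review`. Automated releases do *not*
#' increment validation counters — the counters certify human judgment,
#' and once automated release is running, validation for that analyte is
#' complete.
#'
#' @param session A [lab_session()].
#' @param report A report.
#' @param now Timestamp.
#' @return The updated session; the disposition row is appended to
#'   [dispositions()] and also attached as attribute `"disposition"`.
#' @export
process_report <- function(session, report, now = Sys.time()) {
  stopifnot(inherits(session, "lab_session"))
  report <- if (inherits(report, "av_report")) report else as_report(report)
  w <- evaluate_report(session, report)
  now <- av_time(now)
  outcome <- if (w$barcode_color != "green") {
    "intercepted_for_review"
  } else if (eligible_for_auto_release(session, report, w)) {
    "auto_released"
  } else {
    "manual_release_required"
  }
  disp <- list(barcode = w$barcode, outcome = outcome,
               barcode_color = w$barcode_color, timestamp = now,
               warning = w)
  session$dispositions <- c(session$dispositions, list(disp))
  if (outcome == "auto_released") {
    session <- append_audit(session, "report_released",
                            list(barcode = w$barcode, mode = "automatic",
                                 modified = FALSE),
                            timestamp = now)
  } else {
    session <- append_audit(session, "report_disposed",
                            list(barcode = w$barcode, outcome = outcome,
                                 barcode_color = w$barcode_color),
                            timestamp = now)
  }
  attr(session, "disposition") <- disp
  session
}

#' Release a report by hand
#'
#' The human release path of integrity validation. An unmodified green
#' release certifies the machine once and increments the report's
#' analytes' counters (via [record_release()]); a modified release must
#' carry a modification record — reason and detail — and is dispatched to
#' [record_modification()], clearing counters when the reason indicts the
#' rule set.
#'
#' @param session A [lab_session()].
#' @param report The report being released.
#' @param modified Was any result changed before release?
#' @param modification When `modified`, a list with `analytes`, `reason`
#'   and `detail` (see [record_modification()]).
#' @param now Timestamp.
#' @return The updated session.
#' @export
manual_release <- function(session, report, modified = FALSE,
                           modification = NULL, now = Sys.time()) {
  stopifnot(inherits(session, "lab_session"))
  report <- if (inherits(report, "av_report")) report else as_report(report)
  now <- av_time(now)
  if (modified) {
    if (is.null(modification) || is.null(modification$reason)) {
      abort("a modified release must state the modification reason",
            class = "av_reason_required")
    }
    session <- record_modification(
      session, report,
      analytes = modification$analytes %||% unique(report$analyte_code),
      reason = modification$reason,
      detail = modification$detail %||% "",
      now = now
    )
    session <- append_audit(session, "report_released",
                            list(barcode = report$barcode[[1]],
                                 mode = "manual", modified = TRUE),
                            timestamp = now)
  } else {
    session <- record_release(session, report, modified = FALSE, now = now)
  }
  session
}

coerce_audit <- function(audit) {
  if (inherits(audit, "lab_session")) return(audit_log(audit))
  if (is.character(audit) && length(audit) == 1) return(read_audit_file(audit))
  if (is.data.frame(audit)) {
    need <- c("seq_no", "timestamp", "kind", "payload")
    miss <- setdiff(need, names(audit))
    if (length(miss)) {
      abort(paste0("audit log lacks column(s): ", paste(miss, collapse = ", ")),
            class = "av_bad_input")
    }
    return(as_tibble(audit))
  }
  abort("cannot interpret audit log", class = "av_bad_input")
}

#' Read audit events with filters
#'
#' @param audit A [lab_session()], an [audit_log()] tibble, or the path of
#'   an audit JSONL file.
#' @param kinds Optional character vector of event kinds to keep.
#' @param from,to Optional timestamp bounds (inclusive).
#' @return Tibble of matching events in sequence order.
#' @export
read_audit <- function(audit, kinds = NULL, from = NULL, to = NULL) {
  log <- coerce_audit(audit)
  if (!is.null(kinds)) log <- log[log$kind %in% kinds, , drop = FALSE]
  if (!is.null(from)) log <- log[log$timestamp >= av_time(from), , drop = FALSE]
  if (!is.null(to)) log <- log[log$timestamp <= av_time(to), , drop = FALSE]
  log[order(log$seq_no), , drop = FALSE]
}
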