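#' Start integrity validation for an analyte
#'
#' Creates the analyte's validation counter at zero with a positive target
#' (e.g. 3000 reports, chosen by the laboratory according to review
#' complexity). Allowed only after every non-deleted rule of the analyte
#' has passed correctness verification.
#'
#' @param session A [lab_session()].
#' @param analyte_code Analyte ("project") code.
#' @param target Positive integer validation target.
#' @param now Timestamp.
#' @return The updated session.
#' @export
start_integrity <- function(session, analyte_code, target, now = Sys.time()) {
  stopifnot(inherits(session, "lab_session"))
  if (!is_finite_num(target) || target < 1 || target != floor(target)) {
    abort("target must be a positive integer", class = "av_bad_input")
  }
  if (!is.null(session$counters[[analyte_code]])) {
    abort(paste0("integrity validation already started for ", analyte_code),
          class = "av_duplicate_counter")
  }
  if (!is_project_verified(session, analyte_code)) {
    abort(paste0("analyte ", analyte_code,
                 " has unverified rules; complete correctness first"),
          class = "av_unverified_project")
  }
  session$counters[[analyte_code]] <- list(
    analyte_code = analyte_code, count = 0L, target = as.integer(target),
    auto_enabled = FALSE, cleared_history = list()
  )
  append_audit(session, "counter_started",
               list(analyte_code = analyte_code, target = as.integer(target)),
               timestamp = av_time(now))
}

#' Count an unmodified human release toward integrity validation
#'
#' When staff release a green report without changing anything, the
#' machine's judgment has been certified once, and each of the report's
#' analytes' validation counters increases by one (once per report per
#' analyte). Modified reports never increment — they go through
#' [record_modification()]. Releasing a red report through this path is an
#' error.
#'
#' @param session A [lab_session()].
#' @param report The released report.
#' @param warning Its `av_report_warning`; computed if `NULL`.
#' @param modified Was any result changed before release?
#' @param now Timestamp.
#' @return The updated session.
#' @export
record_release <- function(session, report, warning = NULL, modified = FALSE,
                           now = Sys.time()) {
  stopifnot(inherits(session, "lab_session"))
  report <- if (inherits(report, "av_report")) report else as_report(report)
  warning <- warning %||% evaluate_report(session, report)
  if (warning$barcode_color != "green") {
    abort(paste0("report ", report$barcode[[1]], " is ",
                 warning$barcode_color, "; only green reports can be ",
                 "released through this path"),
          class = "av_not_green")
  }
  now <- av_time(now)
  if (!modified) {
    for (a in unique(report$analyte_code)) {
      ctr <- session$counters[[a]]
      if (is.null(ctr)) next
      ctr$count <- ctr$count + 1L
      if (ctr$count >= ctr$target) ctr$auto_enabled <- TRUE
      session$counters[[a]] <- ctr
      session <- append_audit(session, "counter_incremented",
                              list(analyte_code = a, count = ctr$count),
                              timestamp = now)
    }
  }
  append_audit(session, "report_released",
               list(barcode = report$barcode[[1]], mode = "manual",
                    modified = isTRUE(modified)),
               timestamp = now)
}

modification_reasons <- c(
  a = "rule_execution_error",
  b = "inappropriate_setting",
  c = "new_rule_needed",
  d = "not_autoverification_related",
  e = "warning_prompted_modification"
)

normalize_reason <- function(reason) {
  if (reason %in% names(modification_reasons)) return(reason)
  i <- match(reason, modification_reasons)
  if (is.na(i)) {
    abort(paste0("unknown modification reason: ", reason),
          class = "av_bad_input")
  }
  names(modification_reasons)[i]
}

#' Record a result modification and its reason
#'
#' When a reviewer changes a result the automatic warning had approved,
#' the system demands a reason: (a) rule execution error, (b)
#' inappropriate rule setting, (c) a new rule is needed, (d) unrelated to
#' autoverification, (e) the warning itself prompted the modification.
#' Reasons a-c indict the rule set, so the named analytes' validation
#' counters are cleared to zero and their automated reporting stops;
#' reasons d-e leave counters untouched. The modified content and reason
#' are stored verbatim for later analysis.
#'
#' @param session A [lab_session()].
#' @param report The report being modified.
#' @param analytes Analytes whose results were changed (subset of the
#'   report's analytes).
#' @param reason One of `"a"`..`"e"` or the long reason name.
#' @param detail Free-text description of what was modified; mandatory for
#'   reasons a-c (the analyzable causes).
#' @param now Timestamp.
#' @return The updated session.
#' @export
record_modification <- function(session, report, analytes, reason,
                                detail = "", now = Sys.time()) {
  stopifnot(inherits(session, "lab_session"))
  report <- if (inherits(report, "av_report")) report else as_report(report)
  reason <- normalize_reason(reason)
  missing_analytes <- setdiff(analytes, report$analyte_code)
  if (length(missing_analytes)) {
    abort(paste0("analyte(s) not on report: ",
                 paste(missing_analytes, collapse = ", ")),
          class = "av_bad_input")
  }
  clears <- reason %in% c("a", "b", "c")
  if (clears && (!is_scalar_chr(detail) || !nzchar(detail))) {
    abort("detail is mandatory for reasons a, b and c",
          class = "av_detail_required")
  }
  now <- av_time(now)
  session <- append_audit(session, "modification_recorded",
                          list(barcode = report$barcode[[1]],
                               analytes = analytes, reason = reason,
                               reason_label = modification_reasons[[reason]],
                               detail = detail),
                          timestamp = now)
  if (clears) {
    for (a in analytes) {
      ctr <- session$counters[[a]]
      if (is.null(ctr)) next
      ctr$cleared_history <- c(ctr$cleared_history,
                               list(list(timestamp = now, reason = reason)))
      ctr$count <- 0L
      ctr$auto_enabled <- FALSE
      session$counters[[a]] <- ctr
      session <- append_audit(session, "counter_cleared",
                              list(analyte_code = a, reason = reason),
                              timestamp = now)
    }
  }
  session
}

#' May a report be released automatically?
#'
#' True only when the automated-reporting master switch is on, the
#' report's warning is green, and every analyte on the report has a
#' validation counter that has reached its target with automated
#' reporting still enabled. An analyte with no counter simply makes the
#' report ineligible (manual release), never an error.
#'
#' @param session A [lab_session()].
#' @param report The report.
#' @param warning Its `av_report_warning`; computed if `NULL`.
#' @return Logical scalar.
#' @export
eligible_for_auto_release <- function(session, report, warning = NULL) {
  stopifnot(inherits(session, "lab_session"))
  report <- if (inherits(report, "av_report")) report else as_report(report)
  if (!session$config$master_switch) return(FALSE)
  warning <- warning %||% evaluate_report(session, report)
  if (warning$barcode_color != "green") return(FALSE)
  for (a in unique(report$analyte_code)) {
    ctr <- session$counters[[a]]
    if (is.null(ctr)) return(FALSE)
    if (!ctr$auto_enabled || ctr$count < ctr$target) return(FALSE)
  }
  TRUE
}

#' Reconstruct counter states from an audit log
#'
#' Event-sourcing replay: folds `counter_started`, `counter_incremented`
#' and `counter_cleared` events, in sequence order, into the final
#' per-analyte counter states. Replaying a session's own log reproduces
#' [counters()] exactly.
#'
#' @param audit Audit log: a [lab_session()], a tibble from [audit_log()],
#'   or a JSONL file path.
#' @return Tibble like [counters()] (without `n_cleared` history depth it
#'   includes `n_cleared` as well, derived from clear events).
#' @export
replay_counters <- function(audit) {
  log <- coerce_audit(audit)
  state <- list()
  for (i in seq_len(nrow(log))) {
    kind <- log$kind[i]
    p <- log$payload[[i]]
    if (kind == "counter_started") {
      state[[p$analyte_code]] <- list(count = 0L,
                                      target = as.integer(p$target),
                                      auto_enabled = FALSE, n_cleared = 0L)
    } else if (kind == "counter_incremented") {
      s <- state[[p$analyte_code]]
      s$count <- as.integer(p$count)
      if (s$count >= s$target) s$auto_enabled <- TRUE
      state[[p$analyte_code]] <- s
    } else if (kind == "counter_cleared") {
      s <- state[[p$analyte_code]]
      s$count <- 0L
      s$auto_enabled <- FALSE
      s$n_cleared <- s$n_cleared + 1L
      state[[p$analyte_code]] <- s
    }
  }
  tibble(
    analyte_code = names(state) %||% character(),
    count = unname(map_int(state, "count")),
    target = unname(map_int(state, "target")),
    auto_enabled = unname(map_lgl(state, "auto_enabled")),
    n_cleared = unname(map_int(state, "n_cleared"))
  )
}
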