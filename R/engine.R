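#' Evaluate one warning rule against one test result
#'
#' Applies a rule's interception predicate to a single test. The outcome is
#' deterministic for fixed inputs: `triggered = TRUE` means the rule
#' intercepts the result (contradiction), and `message` then carries the
#' human-readable cause shown on the red warning.
#'
#' @param rule A rule record: either a one-row slice of [rules()] or a list
#'   with fields `rule_id`/`id`, `category`, `params`, `status`.
#' @param test A named list or one-row data frame of one test result.
#' @param history Patient history tibble (used by delta checks).
#' @param panel Tibble of the report's results (used by combined-mode rules).
#' @return Tibble row: `rule_id`, `triggered`, `message`, `rule_status`.
#' @export
#' @examples
#' r <- list(id = "002009", category = "limit_range",
#'           params = validate_rule_params("limit_range",
#'                                         list(intercept_at_or_above = 5)),
#'           status = "pending_verification")
#' evaluate_rule(r, list(value = "1.8", qc_passed = TRUE))
evaluate_rule <- function(rule, test, history = NULL, panel = NULL) {
  rule <- normalize_rule(rule)
  test <- normalize_test(test)
  out <- eval_rule_impl(rule, test, history, panel)
  tibble(rule_id = out$rule_id, triggered = out$triggered,
         message = out$message, rule_status = out$rule_status)
}

normalize_rule <- function(rule) {
  if (is.data.frame(rule)) {
    stopifnot(nrow(rule) == 1)
    rule <- list(id = rule$rule_id[[1]], category = rule$category[[1]],
                 params = rule$params[[1]], scope = rule$scope[[1]],
                 status = rule$status[[1]])
  }
  rule$id <- rule$id %||% rule$rule_id
  rule$status <- rule$status %||% "verified"
  rule
}

normalize_test <- function(test) {
  if (is.data.frame(test)) {
    test <- test_at(as_report(test), 1)
  }
  if (is.character(test$sample_flags) && length(test$sample_flags) == 1 &&
      grepl(";", test$sample_flags %||% "")) {
    test$sample_flags <- parse_flags(test$sample_flags)
  }
  test
}

eval_rule_impl <- function(rule, test, history, panel) {
  if (identical(rule$status, "deleted")) {
    abort("cannot evaluate a deleted rule", class = "av_bad_input")
  }
  pred <- category_predicate(rule$category)
  if (is.null(pred)) {
    abort(paste0("unknown rule category: '", rule$category, "'"),
          class = "av_unknown_category")
  }
  hit <- pred(rule$params, test, history, panel)
  list(
    rule_id = rule$id,
    triggered = hit$triggered,
    message = if (hit$triggered) {
      paste0("rule ", rule$id, " (", rule$category, "): ", hit$cause)
    } else "",
    rule_status = rule$status
  )
}

require_numeric <- function(test, category) {
  v <- numeric_value(test$value)
  if (is.na(v)) {
    abort(paste0(category, " applied to non-numeric value '", test$value, "'"),
          class = "av_type_mismatch")
  }
  v
}

predicate_limit_range <- function(params, test, history, panel) {
  v <- require_numeric(test, "limit_range")
  if (!is.null(params$intercept_above)) {
    hi <- params$intercept_above
    if (if (params$above_inclusive) v >= hi else v > hi) {
      op <- if (params$above_inclusive) ">=" else ">"
      return(list(triggered = TRUE,
                  cause = paste0("result ", v, " ", op, " ", hi)))
    }
  }
  if (!is.null(params$intercept_below)) {
    lo <- params$intercept_below
    if (if (params$below_inclusive) v <= lo else v < lo) {
      op <- if (params$below_inclusive) "<=" else "<"
      return(list(triggered = TRUE,
                  cause = paste0("result ", v, " ", op, " ", lo)))
    }
  }
  list(triggered = FALSE, cause = "")
}

predicate_delta_check <- function(params, test, history, panel) {
  v <- require_numeric(test, "delta_check")
  prior <- history_lookup(history, test$patient_id, test$analyte_code,
                          test$collection_time, params$lookback_days)
  if (nrow(prior) == 0) {
    if (params$trigger_when_no_history) {
      return(list(triggered = TRUE, cause = "no prior result in lookback window"))
    }
    return(list(triggered = FALSE, cause = ""))
  }
  p <- prior$value[[1]]
  if (identical(params$mode, "absolute")) {
    d <- abs(v - p)
    if (d > params$threshold) {
      return(list(triggered = TRUE,
                  cause = paste0("absolute delta ", d, " > ", params$threshold)))
    }
  } else {
    if (p == 0) {
      # no ratio against a zero prior; absolute fallback keeps the check live
      if (abs(v) > params$zero_fallback) {
        return(list(triggered = TRUE,
                    cause = paste0("delta from zero prior ", abs(v), " > ",
                                   params$zero_fallback)))
      }
    } else {
      pc <- abs(v - p) / abs(p) * 100
      if (pc > params$threshold) {
        return(list(triggered = TRUE,
                    cause = paste0("delta ", round(pc, 1), "% > ",
                                   params$threshold, "%")))
      }
    }
  }
  list(triggered = FALSE, cause = "")
}

predicate_combined_mode <- function(params, test, history, panel) {
  if (is.null(panel)) {
    abort("combined_mode rule needs the report panel", class = "av_bad_input")
  }
  vals <- character(length(params$panel_analytes))
  names(vals) <- params$panel_analytes
  for (a in params$panel_analytes) {
    i <- match(a, panel$analyte_code)
    if (is.na(i)) {
      abort(paste0("panel member absent from report: ", a),
            class = "av_missing_panel_member")
    }
    vals[[a]] <- as.character(panel$value[i])
  }
  pat <- params$patterns
  for (r in seq_len(nrow(pat))) {
    # case-sensitive exact match of the joint qualitative pattern
    if (all(vals == unlist(pat[r, params$panel_analytes]))) {
      if (pat$flag[r] == "contradictory") {
        return(list(triggered = TRUE,
                    cause = paste0("contradictory pattern: ",
                                   paste(names(vals), vals, sep = "=",
                                         collapse = ", "))))
      }
      return(list(triggered = FALSE, cause = ""))
    }
  }
  if (identical(params$unlisted_policy, "intercept")) {
    return(list(triggered = TRUE,
                cause = paste0("pattern not covered by mode table: ",
                               paste(names(vals), vals, sep = "=",
                                     collapse = ", "))))
  }
  list(triggered = FALSE, cause = "")
}

clock_minutes <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60 + lt$min
}

hhmm_minutes <- function(s) {
  p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

predicate_sampling_time <- function(params, test, history, panel) {
  m <- clock_minutes(test$collection_time)
  lo <- hhmm_minutes(params$window_start)
  hi <- hhmm_minutes(params$window_end)
  inside <- if (lo <= hi) m >= lo & m <= hi else m >= lo | m <= hi
  if (!inside) {
    return(list(triggered = TRUE,
                cause = paste0("collected at ",
                               format(test$collection_time, "%H:%M", tz = "UTC"),
                               ", outside ", params$window_start, "-",
                               params$window_end)))
  }
  list(triggered = FALSE, cause = "")
}

predicate_sample_abnormality <- function(params, test, history, panel) {
  hit <- intersect(params$intercept_on, test$sample_flags)
  if (length(hit)) {
    return(list(triggered = TRUE,
                cause = paste0("sample flagged: ", paste(hit, collapse = ", "))))
  }
  list(triggered = FALSE, cause = "")
}

predicate_qc_check <- function(params, test, history, panel) {
  if (!isTRUE(test$qc_passed)) {
    return(list(triggered = TRUE, cause = "quality control not passed"))
  }
  list(triggered = FALSE, cause = "")
}

#' Delta check against a patient's prior result
#'
#' Convenience wrapper exposing the delta-check predicate directly: the
#' current value is compared with the most recent prior value inside the
#' lookback window, as an absolute difference or a percent change.
#'
#' @param params Delta parameters (see [validate_rule_params()] with
#'   category `"delta_check"`): `mode` ("percent" or "absolute"),
#'   `threshold`, `lookback_days`, `trigger_when_no_history`,
#'   `zero_fallback`.
#' @param test One test result (named list or one-row data frame).
#' @param history Patient history tibble.
#' @return Tibble row `triggered`, `message`.
#' @export
check_delta <- function(params, test, history) {
  params <- validate_rule_params("delta_check", params)
  test <- normalize_test(test)
  hit <- predicate_delta_check(params, test, history, NULL)
  tibble(triggered = hit$triggered, message = hit$cause)
}

#' Combined-mode (panel consistency) check
#'
#' Evaluates the joint qualitative pattern of a multi-marker panel against
#' a mode table whose rows are flagged `contradictory` or `allowed`.
#' Patterns absent from the table are governed by `unlisted_policy`
#' (default `"intercept"`: an uncovered scenario goes to a human).
#'
#' @param params Combined-mode parameters: `panel_analytes`, `patterns`
#'   (data frame with one column per analyte plus `flag`), `unlisted_policy`.
#' @param panel Tibble of the report's results.
#' @return Tibble row `triggered`, `message`.
#' @export
check_combined_mode <- function(params, panel) {
  params <- validate_rule_params("combined_mode", params)
  hit <- predicate_combined_mode(params, NULL, NULL, panel)
  tibble(triggered = hit$triggered, message = hit$cause)
}

rule_applies <- function(rule, test) {
  sc <- rule$scope
  if (is.null(sc)) return(TRUE)
  if (!is.null(sc$detection_systems) &&
      !(test$detection_system %in% sc$detection_systems)) {
    return(FALSE)
  }
  if (!is.null(sc$specimen_types) &&
      !(test$specimen_type %in% sc$specimen_types)) {
    return(FALSE)
  }
  TRUE
}

# Evaluate all applicable rules for one test; internal hot path.
eval_test_impl <- function(session, test, panel) {
  ids <- session$by_analyte[[test$analyte_code]]
  outcomes <- list()
  any_triggered <- FALSE
  any_pending <- FALSE
  k <- 0L
  for (id in ids) {
    rule <- session$rules[[id]]
    if (rule$status == "deleted") next
    if (!rule_applies(rule, test)) next
    out <- eval_rule_impl(rule, test, session$history, panel)
    k <- k + 1L
    outcomes[[k]] <- out
    if (out$triggered) any_triggered <- TRUE
    if (rule$status == "pending_verification") any_pending <- TRUE
  }
  if (k == 0L) {
    # fail-safe: a test no rule covers is never allowed to auto-pass
    return(list(analyte_code = test$analyte_code, barcode = test$barcode,
                color = "red", outcomes = list(),
                no_rules = TRUE))
  }
  color <- if (any_triggered) "red" else if (any_pending) "purple" else "green"
  list(analyte_code = test$analyte_code, barcode = test$barcode,
       color = color, outcomes = outcomes, no_rules = FALSE)
}

#' Evaluate every rule for every test of a report
#'
#' The automatic-warning stage. Each test is evaluated against all
#' applicable non-deleted rules (the report's own results serve as the
#' combined-mode panel) and coloured: red if any rule intercepts it,
#' purple if nothing intercepts but some applicable rule is still pending
#' verification, green otherwise. A test with no applicable rule at all is
#' red (manual review; nothing auto-passes unruled). The barcode colour
#' summarises the report: green only if every test is green, red if any
#' test is red, purple otherwise.
#'
#' @param session A [lab_session()] carrying the rule set and history.
#' @param report A report (see [as_report()]).
#' @return An object of class `av_report_warning`: list with `barcode`,
#'   `barcode_color`, `tests` (tibble: `analyte_code`, `color`,
#'   `n_triggered`, `n_pending`) and `outcomes` (tibble of every rule
#'   outcome).
#' @export
evaluate_report <- function(session, report) {
  stopifnot(inherits(session, "lab_session"))
  report <- if (inherits(report, "av_report")) report else as_report(report)
  tw <- lapply(seq_len(nrow(report)), function(i) {
    eval_test_impl(session, test_at(report, i), report)
  })
  colors <- map_chr(tw, "color")
  barcode_color <- if (any(colors == "red")) "red"
  else if (all(colors == "green")) "green"
  else "purple"
  outcomes <- bind_rows(lapply(tw, function(w) {
    if (!length(w$outcomes)) return(NULL)
    tibble(
      analyte_code = w$analyte_code,
      rule_id = map_chr(w$outcomes, "rule_id"),
      triggered = map_lgl(w$outcomes, "triggered"),
      message = map_chr(w$outcomes, "message"),
      rule_status = map_chr(w$outcomes, "rule_status")
    )
  }))
  if (nrow(outcomes) == 0) {
    outcomes <- tibble(analyte_code = character(), rule_id = character(),
                       triggered = logical(), message = character(),
                       rule_status = character())
  }
  structure(list(
    barcode = report$barcode[[1]],
    barcode_color = barcode_color,
    tests = tibble(
      analyte_code = map_chr(tw, "analyte_code"),
      color = colors,
      n_triggered = map_int(tw, ~ sum(map_lgl(.x$outcomes, "triggered"))),
      n_pending = map_int(tw, ~ sum(map_chr(.x$outcomes, "rule_status") ==
                                      "pending_verification"))
    ),
    outcomes = outcomes
  ), class = "av_report_warning")
}

#' @export
print.av_report_warning <- function(x, ...) {
  cat("<report warning> barcode", x$barcode, "->", x$barcode_color, "\n")
  print(x$tests)
  invisible(x)
}

#' Evaluate a whole result stream
#'
#' Tidy surface over [evaluate_report()]: groups a result stream by
#' barcode and returns one row per test with its warning colour.
#'
#' @param session A [lab_session()].
#' @param results Tibble of test-result rows (any number of barcodes).
#' @return Tibble: `barcode`, `analyte_code`, `color`, `barcode_color`,
#'   `n_triggered`, `messages` (collapsed cause strings).
#' @export
evaluate_results <- function(session, results) {
  sp <- split_reports(results)
  rows <- lapply(sp$reports, function(rep) {
    w <- evaluate_report(session, rep)
    msgs <- vapply(w$tests$analyte_code, function(a) {
      m <- w$outcomes$message[w$outcomes$analyte_code == a &
                                w$outcomes$triggered]
      paste(m, collapse = " | ")
    }, character(1))
    tibble(barcode = w$barcode, analyte_code = w$tests$analyte_code,
           color = w$tests$color, barcode_color = w$barcode_color,
           n_triggered = w$tests$n_triggered, messages = unname(msgs))
  })
  bind_rows(rows)
}

#' Evaluate a report and log pending-rule validations
#'
#' Like [evaluate_report()], but additionally appends one `rule_evaluated`
#' audit event per (pending rule, test) execution — the unit the
#' correctness-verification statistics count as a "validation". The event
#' payload records whether that execution released (did not trigger) or
#' intercepted (triggered) the test.
#'
#' @param session A [lab_session()].
#' @param report A report.
#' @return The updated session; the computed warning is attached as
#'   attribute `"warning"`.
#' @export
session_evaluate <- function(session, report) {
  report <- if (inherits(report, "av_report")) report else as_report(report)
  w <- evaluate_report(session, report)
  pend <- w$outcomes[w$outcomes$rule_status == "pending_verification", ,
                     drop = FALSE]
  if (nrow(pend)) {
    for (i in seq_len(nrow(pend))) {
      session <- append_audit(session, "rule_evaluated", list(
        rule_id = pend$rule_id[i],
        barcode = w$barcode,
        analyte_code = pend$analyte_code[i],
        outcome = if (pend$triggered[i]) "intercepted" else "released"
      ))
    }
  }
  attr(session, "warning") <- w
  session
}
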