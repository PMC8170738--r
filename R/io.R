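#' Save rule definitions to JSON
#'
#' Writes rules as a JSON array (one object per rule: `rule_id`,
#' `analyte_code`, `category`, `params`, `scope`, `status`). Output is
#' deterministic: fixed key order, no digit truncation.
#'
#' @param x A [lab_session()] or a rule-definitions tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ruleset <- function(x, path) {
  defs <- if (inherits(x, "lab_session")) rules(x) else as_tibble(x)
  objs <- lapply(seq_len(nrow(defs)), function(i) {
    o <- list(rule_id = defs$rule_id[i],
              analyte_code = defs$analyte_code[i],
              category = defs$category[i],
              params = defs$params[[i]])
    if ("scope" %in% names(defs) && !is.null(defs$scope[[i]])) {
      o$scope <- defs$scope[[i]]
    }
    if ("status" %in% names(defs)) o$status <- defs$status[i]
    o
  })
  writeLines(jsonlite::toJSON(objs, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' Load rule definitions from JSON
#'
#' Schema-checks every rule on the way in: the six built-in categories are
#' matched case-sensitively (a mis-cased `"Limit_Range"` is rejected, with
#' the offending rule named), parameters are validated and normalised, and
#' duplicate ids are an error. An empty file yields an empty rule set with
#' a warning.
#'
#' @param path JSON file of rule definitions.
#' @return Tibble: `rule_id`, `analyte_code`, `category`, `params`,
#'   `scope`, `status`.
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "av_io_error")
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  empty <- tibble(rule_id = character(), analyte_code = character(),
                  category = character(), params = list(), scope = list(),
                  status = character())
  if (!nzchar(trimws(txt))) {
    warn("empty rule file; returning an empty rule set")
    return(empty)
  }
  raw <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!length(raw)) {
    warn("empty rule file; returning an empty rule set")
    return(empty)
  }
  parse_one <- function(o, i) {
    for (f in c("rule_id", "analyte_code", "category")) {
      if (is.null(o[[f]])) {
        abort(paste0("rule #", i, ": missing field '", f, "'"),
              class = "av_schema_error")
      }
    }
    params <- o$params %||% list()
    # JSON arrays of scalars come back as lists; flatten to atomic vectors
    for (nm in setdiff(names(params), "patterns")) {
      el <- params[[nm]]
      if (is.list(el) &&
          all(vapply(el, function(x) is.atomic(x) && length(x) == 1,
                     logical(1)))) {
        params[[nm]] <- unlist(el)
      }
    }
    if (!is.null(params$patterns)) {
      params$patterns <- as.data.frame(
        do.call(rbind, lapply(params$patterns, function(r) {
          unlist(r, use.names = TRUE)
        })), stringsAsFactors = FALSE)
    }
    params <- withCallingHandlers(
      tryCatch(validate_rule_params(o$category, params),
               error = function(e) {
                 abort(paste0("rule #", i, " (", o$rule_id, "): ",
                              conditionMessage(e)),
                       class = "av_schema_error")
               }),
      warning = function(w) invokeRestart("muffleWarning"))
    scope <- o$scope
    if (!is.null(scope)) scope <- lapply(scope, function(s) unlist(s))
    list(rule_id = o$rule_id, analyte_code = o$analyte_code,
         category = o$category, params = params, scope = scope,
         status = o$status %||% "pending_verification")
  }
  parsed <- lapply(seq_along(raw), function(i) parse_one(raw[[i]], i))
  ids <- map_chr(parsed, "rule_id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate rule id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "av_schema_error")
  }
  tibble(
    rule_id = ids,
    analyte_code = map_chr(parsed, "analyte_code"),
    category = map_chr(parsed, "category"),
    params = map(parsed, "params"),
    scope = map(parsed, "scope"),
    status = map_chr(parsed, "status")
  )
}

#' Load a result stream
#'
#' Reads test-result rows from CSV (header required, ISO-8601 timestamps)
#' or JSONL, groups them by barcode into reports and validates each
#' report. Rows belonging to an invalid group (receipt before collection,
#' duplicate analyte on one barcode, ...) are returned in `rejected` with
#' a reason — never dropped silently.
#'
#' @param path CSV or JSONL file.
#' @return List: `reports` (named list of `av_report`), `rejected`
#'   (tibble with `reject_reason`).
#' @export
load_results <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "av_io_error")
  }
  df <- if (grepl("\\.jsonl$", path)) {
    bind_rows(lapply(readLines(path, warn = FALSE), function(l) {
      as_tibble(jsonlite::fromJSON(l))
    }))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("barcode", "patient_id", "analyte_code", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("results lack column(s): ", paste(miss, collapse = ", ")),
          class = "av_schema_error")
  }
  df$barcode <- as.character(df$barcode)
  df$value <- as.character(df$value)
  split_reports(df)
}

#' Load a patient history table
#'
#' @param path CSV with columns `patient_id`, `analyte_code`, `value`,
#'   `collection_time`.
#' @return Normalised history data frame, time-ordered per patient.
#' @export
load_history <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "av_io_error")
  }
  as_history(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write an audit log as JSONL
#'
#' One event per line, stable key order, ISO-8601 timestamps; the file is
#' byte-stable for identical logs.
#'
#' @param audit A [lab_session()] or [audit_log()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  log <- coerce_audit(audit)
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(list(seq_no = log$seq_no[i],
                          timestamp = format_time(log$timestamp[i]),
                          kind = log$kind[i],
                          payload = log$payload[[i]]),
                     auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_audit_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "av_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  evs <- lapply(seq_along(lines), function(i) {
    ev <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                   error = function(e) NULL)
    if (is.null(ev) || is.null(ev$seq_no) || is.null(ev$kind)) {
      abort(paste0("corrupt audit line ", i, " in ", path),
            class = "av_corrupt_audit")
    }
    ev
  })
  tibble(
    seq_no = map_int(evs, ~ as.integer(.x$seq_no)),
    timestamp = av_time(map_chr(evs, "timestamp")),
    kind = map_chr(evs, "kind"),
    payload = map(evs, "payload")
  )
}

#' Write warning rows as JSONL
#'
#' @param warnings Tibble from [evaluate_results()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_warnings <- function(warnings, path) {
  lines <- vapply(seq_len(nrow(warnings)), function(i) {
    jsonlite::toJSON(as.list(warnings[i, ]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Rebuild a session from serialised state
#'
#' Deserialisation path for the command-line pipeline: registers the
#' rules, restores their persisted lifecycle statuses verbatim (this is a
#' load, not a judgment — no audit events besides registration are
#' fabricated) and re-creates counters.
#'
#' @param rule_defs Rule definitions tibble (with optional `status`).
#' @param history Optional history table.
#' @param counters Optional counters tibble (`analyte_code`, `count`,
#'   `target`, `auto_enabled`).
#' @param master_switch Logical.
#' @return A [lab_session()].
#' @export
restore_session <- function(rule_defs, history = NULL, counters = NULL,
                            master_switch = FALSE) {
  session <- lab_session(history = history, master_switch = master_switch)
  session <- register_rules(session, rule_defs)
  if ("status" %in% names(rule_defs)) {
    for (i in seq_len(nrow(rule_defs))) {
      st <- rule_defs$status[i]
      if (!is.na(st) && st != "pending_verification") {
        session$rules[[rule_defs$rule_id[i]]]$status <- st
      }
    }
  }
  if (!is.null(counters)) {
    for (i in seq_len(nrow(counters))) {
      a <- counters$analyte_code[i]
      session$counters[[a]] <- list(
        analyte_code = a,
        count = as.integer(counters$count[i]),
        target = as.integer(counters$target[i]),
        auto_enabled = isTRUE(counters$auto_enabled[i]),
        cleared_history = list()
      )
    }
  }
  session
}

#' Save integrity counters as JSON
#'
#' @param session A [lab_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_counters <- function(session, path) {
  writeLines(jsonlite::toJSON(counters(session), dataframe = "rows",
                              auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

#' Load integrity counters from JSON
#'
#' @param path JSON file written by [save_counters()].
#' @return Counters tibble.
#' @export
load_counters <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "av_io_error")
  }
  as_tibble(jsonlite::fromJSON(path))
}
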