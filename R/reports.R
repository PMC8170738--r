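#' Construct and validate a report
#'
#' A report is the unit of warning and release: all test results sharing
#' one specimen barcode. `as_report()` checks the container invariants —
#' a single barcode and patient, no duplicate analyte, receipt never before
#' collection, finite numeric values — and normalises column types.
#'
#' @param results Data frame of test results with columns `barcode`,
#'   `patient_id`, `analyte_code`, `value`, and optionally `units`,
#'   `collection_time`, `receipt_time`, `qc_passed`, `sample_flags`
#'   (";"-separated), `detection_system`, `specimen_type`.
#' @return A tibble of class `av_report`.
#' @export
#' @examples
#' as_report(tibble::tibble(
#'   barcode = "B001", patient_id = "P1", analyte_code = "CRP",
#'   value = "1.8", units = "mg/l", qc_passed = TRUE
#' ))
as_report <- function(results) {
  r <- as_tibble(results)
  need <- c("barcode", "patient_id", "analyte_code", "value")
  miss <- setdiff(need, names(r))
  if (length(miss)) {
    abort(paste0("report lacks column(s): ", paste(miss, collapse = ", ")),
          class = "av_bad_report")
  }
  if (nrow(r) == 0) abort("report is empty", class = "av_bad_report")
  if (length(unique(r$barcode)) != 1 || length(unique(r$patient_id)) != 1) {
    abort("all results in a report must share one barcode and patient",
          class = "av_bad_report")
  }
  if (anyDuplicated(r$analyte_code)) {
    abort("duplicate analyte in report", class = "av_bad_report")
  }
  r$value <- as.character(r$value)
  if (!"units" %in% names(r)) r$units <- NA_character_
  if (!"collection_time" %in% names(r)) r$collection_time <- av_time("2000-01-01 00:00")
  r$collection_time <- av_time(r$collection_time)
  if (!"receipt_time" %in% names(r)) r$receipt_time <- r$collection_time
  r$receipt_time <- av_time(r$receipt_time)
  if (any(r$receipt_time < r$collection_time)) {
    abort("receipt_time before collection_time", class = "av_bad_report")
  }
  if (!"qc_passed" %in% names(r)) r$qc_passed <- TRUE
  r$qc_passed <- as.logical(r$qc_passed)
  if (!"sample_flags" %in% names(r)) r$sample_flags <- ""
  r$sample_flags[is.na(r$sample_flags)] <- ""
  bad_flags <- setdiff(unlist(lapply(r$sample_flags, parse_flags)),
                       c("hemolysis", "lipemia"))
  if (length(bad_flags)) {
    abort(paste0("unknown sample flag(s): ", paste(bad_flags, collapse = ", ")),
          class = "av_bad_report")
  }
  if (!"detection_system" %in% names(r)) r$detection_system <- NA_character_
  if (!"specimen_type" %in% names(r)) r$specimen_type <- NA_character_
  class(r) <- c("av_report", class(r))
  r
}

# One test row as a plain named list (engine hot path works on lists).
test_at <- function(report, i) {
  list(
    barcode = report$barcode[i],
    patient_id = report$patient_id[i],
    analyte_code = report$analyte_code[i],
    value = report$value[i],
    units = report$units[i],
    collection_time = report$collection_time[i],
    receipt_time = report$receipt_time[i],
    qc_passed = report$qc_passed[i],
    sample_flags = parse_flags(report$sample_flags[i]),
    detection_system = report$detection_system[i],
    specimen_type = report$specimen_type[i]
  )
}

#' Split a result stream into reports
#'
#' Groups a tibble of test-result rows by barcode and validates each group
#' with [as_report()]. Rows whose group violates a report invariant are
#' collected into a reject tibble rather than dropped silently.
#'
#' @param results Tibble of test-result rows (multiple barcodes).
#' @return List with elements `reports` (list of `av_report`) and
#'   `rejected` (tibble of offending rows with a `reject_reason` column).
#' @export
split_reports <- function(results) {
  results <- as_tibble(results)
  groups <- split(results, results$barcode)
  reports <- list()
  rejected <- list()
  for (bc in names(groups)) {
    rep <- tryCatch(as_report(groups[[bc]]), error = function(e) e)
    if (inherits(rep, "error")) {
      g <- groups[[bc]]
      g$reject_reason <- conditionMessage(rep)
      rejected[[bc]] <- g
    } else {
      reports[[bc]] <- rep
    }
  }
  list(reports = reports, rejected = bind_rows(rejected))
}
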