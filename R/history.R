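#' Look up a patient's most recent prior result
#'
#' Returns the latest history entry for one analyte whose collection time
#' falls in the half-open window `[as_of - lookback_days, as_of)`. The
#' current result itself (collected exactly at `as_of`) is never its own
#' prior. An empty window is a value, not an error: delta checks treat "no
#' prior" as configurable behaviour, not a failure.
#'
#' @param history History tibble with columns `patient_id`, `analyte_code`,
#'   `value`, `collection_time`.
#' @param patient_id Patient identifier.
#' @param analyte_code Analyte code.
#' @param as_of Timestamp of the current result.
#' @param lookback_days Window length in days; must be > 0.
#' @return One-row tibble (`value`, `collection_time`) or a zero-row tibble
#'   when no prior entry exists in the window.
#' @export
#' @examples
#' h <- tibble::tibble(patient_id = "P1", analyte_code = "HGB",
#'                     value = c(118, 131),
#'                     collection_time = c("2023-05-01 08:00", "2023-05-03 08:00"))
#' history_lookup(h, "P1", "HGB", "2023-05-04 08:00", lookback_days = 7)
history_lookup <- function(history, patient_id, analyte_code, as_of,
                           lookback_days = 7) {
  if (!is_finite_num(lookback_days) || lookback_days <= 0) {
    abort("lookback_days must be > 0", class = "av_bad_input")
  }
  empty <- tibble(value = numeric(), collection_time = av_time(character()))
  if (is.null(history) || nrow(history) == 0) return(empty)
  h <- history
  as_of <- av_time(as_of)
  lo <- as_of - lookback_days * 86400
  ct <- av_time(h$collection_time)
  keep <- h$patient_id == patient_id & h$analyte_code == analyte_code &
    ct >= lo & ct < as_of
  if (!any(keep)) return(empty)
  idx <- which(keep)
  best <- idx[which.max(as.numeric(ct[idx]))]
  tibble(value = as.numeric(h$value[best]), collection_time = ct[best])
}
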