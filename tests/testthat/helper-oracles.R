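# Independent straight-line reimplementations of each interception
# predicate, written directly from their definitions and kept free of any
# package internals. Property tests compare engine outcomes against these.

oracle_limit <- function(v, above, below, above_incl, below_incl) {
  hit <- FALSE
  if (!is.null(above)) {
    hit <- hit || (if (above_incl) v >= above else v > above)
  }
  if (!is.null(below)) {
    hit <- hit || (if (below_incl) v <= below else v < below)
  }
  hit
}

oracle_delta <- function(v, prior_values, prior_times, as_of, lookback_days,
                         mode, threshold, zero_fallback, trigger_no_history) {
  lo <- as_of - lookback_days * 86400
  inwin <- prior_times >= lo & prior_times < as_of
  if (!any(inwin)) return(trigger_no_history)
  p <- prior_values[inwin][which.max(as.numeric(prior_times[inwin]))]
  if (mode == "absolute") return(abs(v - p) > threshold)
  if (p == 0) return(abs(v) > zero_fallback)
  abs(v - p) / abs(p) * 100 > threshold
}

oracle_sampling <- function(minute_of_day, start_min, end_min) {
  inside <- if (start_min <= end_min) {
    minute_of_day >= start_min && minute_of_day <= end_min
  } else {
    minute_of_day >= start_min || minute_of_day <= end_min
  }
  !inside
}

oracle_abnormality <- function(flags, intercept_on) {
  any(intercept_on %in% flags)
}

oracle_qc <- function(qc_passed) !isTRUE(qc_passed)

oracle_combined <- function(values, table_rows, table_flags, unlisted_policy) {
  for (i in seq_along(table_flags)) {
    if (all(values == table_rows[[i]])) {
      return(table_flags[i] == "contradictory")
    }
  }
  unlisted_policy == "intercept"
}

# Brute-force prior-result lookup used against history_lookup().
oracle_history <- function(h, pid, analyte, as_of, lookback_days) {
  keep <- h$patient_id == pid & h$analyte_code == analyte &
    h$collection_time >= as_of - lookback_days * 86400 &
    h$collection_time < as_of
  if (!any(keep)) return(NULL)
  sub <- h[keep, , drop = FALSE]
  sub$value[which.max(as.numeric(sub$collection_time))]
}
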