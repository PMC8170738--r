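# Shared builders for sessions, reports and rules used across test files.

map_chr_safe <- function(l, f) {
  vapply(l, function(x) {
    v <- x[[f]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
}

T0 <- as.POSIXct("2023-05-10 08:00:00", tz = "UTC")

one_test_report <- function(barcode, analyte = "CRP", value = "1.8",
                            qc = TRUE, flags = "", patient = "P0001",
                            collection = T0, dsys = "AU5800") {
  as_report(tibble::tibble(
    barcode = barcode, patient_id = patient, analyte_code = analyte,
    value = as.character(value), units = "mg/l",
    collection_time = collection, receipt_time = collection + 1800,
    qc_passed = qc, sample_flags = flags, detection_system = dsys
  ))
}

# Session holding the worked CRP example: a verified QC rule (001879) and a
# pending limit rule (002009) intercepting results >= 5 mg/l.
crp_session <- function() {
  lab_session() |>
    register_rule("001879", "CRP", "qc_check", now = T0 - 86400 * 30) |>
    record_judgment("001879", "SEED-QC", "consistent", now = T0 - 86400 * 29) |>
    register_rule("002009", "CRP", "limit_range",
                  list(intercept_at_or_above = 5, units = "mg/l"), now = T0)
}

# Session with one verified limit rule on one analyte, counters optional.
verified_session <- function(analyte = "CRP", target = NULL,
                             master_switch = FALSE) {
  s <- lab_session(master_switch = master_switch) |>
    register_rule("000001", analyte, "limit_range",
                  list(intercept_at_or_above = 5), now = T0) |>
    record_judgment("000001", "SEED-1", "consistent", now = T0)
  if (!is.null(target)) s <- start_integrity(s, analyte, target, now = T0)
  s
}

hbv_panel_report <- function(barcode, values, patient = "P0001") {
  markers <- c("HBsAg", "HBsAb", "HBeAg", "HBeAb", "HBcAb")
  as_report(tibble::tibble(
    barcode = barcode, patient_id = patient, analyte_code = markers,
    value = values, collection_time = T0, receipt_time = T0 + 1800,
    qc_passed = TRUE, detection_system = "I2000SR"
  ))
}
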