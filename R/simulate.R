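#' Default synthetic analyte catalog
#'
#' A small catalog mixing quantitative chemistry/hematology analytes with
#' the five-marker hepatitis B serology panel: C-reactive protein, albumin,
#' urea, hemoglobin, cortisol (a circadian-rhythm analyte drawn in a
#' morning window), and HBsAg/HBsAb/HBeAg/HBeAb/HBcAb.
#'
#' @return Tibble: `code`, `name`, `units`, `panel`, `kind`.
#' @export
default_catalog <- function() {
  tibble(
    code = c("CRP", "ALB", "UREA", "HGB", "CORT",
             "HBsAg", "HBsAb", "HBeAg", "HBeAb", "HBcAb"),
    name = c("C-reactive protein", "Albumin", "Urea", "Hemoglobin",
             "Cortisol", "HBV surface antigen", "HBV surface antibody",
             "HBV e antigen", "HBV e antibody", "HBV core antibody"),
    units = c("mg/l", "g/l", "mmol/l", "g/l", "nmol/l",
              rep(NA_character_, 5)),
    panel = c(rep(NA_character_, 5), rep("HBV", 5)),
    kind = c(rep("quantitative", 5), rep("categorical", 5))
  )
}

hbv_markers <- c("HBsAg", "HBsAb", "HBeAg", "HBeAb", "HBcAb")

hbv_row <- function(sAg, sAb, eAg, eAb, cAb, ...) {
  pn <- function(x) if (x) "positive" else "negative"
  c(HBsAg = pn(sAg), HBsAb = pn(sAb), HBeAg = pn(eAg),
    HBeAb = pn(eAb), HBcAb = pn(cAb))
}

#' Default HBV serology joint-pattern frequency table
#'
#' Generation frequencies over the five-marker pattern space, concentrated
#' on the biologically common serostatus patterns (susceptible, vaccinated,
#' resolved infection, "big three", "small three", isolated core
#' antibody). These are simulation defaults, not prevalence claims.
#'
#' @return Data frame: one column per marker plus `prob`.
#' @export
default_hbv_frequencies <- function() {
  pat <- rbind(
    hbv_row(FALSE, FALSE, FALSE, FALSE, FALSE), # susceptible
    hbv_row(FALSE, TRUE,  FALSE, FALSE, FALSE), # vaccinated
    hbv_row(FALSE, TRUE,  FALSE, FALSE, TRUE),  # resolved, sAb+cAb
    hbv_row(FALSE, TRUE,  FALSE, TRUE,  TRUE),  # resolved, eAb+cAb
    hbv_row(TRUE,  FALSE, TRUE,  FALSE, TRUE),  # "big three"
    hbv_row(TRUE,  FALSE, FALSE, TRUE,  TRUE),  # "small three"
    hbv_row(FALSE, FALSE, FALSE, FALSE, TRUE)   # isolated core antibody
  )
  out <- as.data.frame(pat, stringsAsFactors = FALSE)
  out$prob <- c(0.50, 0.18, 0.08, 0.05, 0.06, 0.10, 0.03)
  out
}

#' Default HBV combined-mode pattern table
#'
#' The mode table used by the built-in combined-mode rule: simultaneous
#' surface antigen and surface antibody positivity is contradictory, the
#' common serostatus patterns are allowed, and anything unlisted is
#' intercepted for human review.
#'
#' @return Data frame: one column per marker plus `flag`.
#' @export
default_hbv_mode_table <- function() {
  freq <- default_hbv_frequencies()
  allowed <- freq[, hbv_markers]
  allowed$flag <- "allowed"
  contra <- as.data.frame(rbind(
    hbv_row(TRUE, TRUE, FALSE, FALSE, FALSE),
    hbv_row(TRUE, TRUE, FALSE, FALSE, TRUE),
    hbv_row(TRUE, TRUE, TRUE, FALSE, TRUE)
  ), stringsAsFactors = FALSE)
  contra$flag <- "contradictory"
  rbind(allowed, contra)
}

default_analyte_specs <- function() {
  list(
    CRP  = list(meanlog = log(2.0), sdlog = 0.60),
    ALB  = list(meanlog = log(45), sdlog = 0.08),
    UREA = list(meanlog = log(5.0), sdlog = 0.25),
    HGB  = list(meanlog = log(140), sdlog = 0.10),
    CORT = list(meanlog = log(350), sdlog = 0.35)
  )
}

#' Default synthetic rule definitions
#'
#' Builds the rule set a laboratory would register over
#' [default_catalog()]: a quality-control gate on every analyte, limit
#' ranges on the quantitative analytes, a percent delta check on
#' hemoglobin, a morning sampling-time window on cortisol, a hemolysis
#' interception on albumin scoped to its detection system, and the HBV
#' combined-mode rule.
#'
#' @return Tibble of rule definitions: `rule_id`, `analyte_code`,
#'   `category`, `params` (list), `scope` (list).
#' @export
default_rule_definitions <- function() {
  cat <- default_catalog()
  defs <- list()
  add <- function(analyte, category, params = list(), scope = NULL) {
    defs[[length(defs) + 1]] <<- list(analyte_code = analyte,
                                      category = category,
                                      params = params, scope = scope)
  }
  for (a in cat$code) add(a, "qc_check")
  add("CRP", "limit_range", list(intercept_at_or_above = 5, units = "mg/l"))
  add("ALB", "limit_range", list(intercept_below = 35, intercept_above = 55,
                                 below_inclusive = FALSE,
                                 above_inclusive = FALSE, units = "g/l"))
  add("UREA", "limit_range", list(intercept_below = 2.8, intercept_above = 7.2,
                                  below_inclusive = FALSE,
                                  above_inclusive = FALSE, units = "mmol/l"))
  add("HGB", "limit_range", list(intercept_below = 115, intercept_above = 175,
                                 below_inclusive = FALSE,
                                 above_inclusive = FALSE, units = "g/l"))
  add("CORT", "limit_range", list(intercept_below = 80, intercept_above = 700,
                                  below_inclusive = FALSE,
                                  above_inclusive = FALSE, units = "nmol/l"))
  add("HGB", "delta_check", list(mode = "percent", threshold = 25,
                                 lookback_days = 7))
  add("CORT", "sampling_time_validity", list(window_start = "06:00",
                                             window_end = "10:00"))
  add("ALB", "sample_abnormality", list(intercept_on = "hemolysis"),
      scope = list(detection_systems = "AU5800"))
  add("HBsAg", "combined_mode", list(panel_analytes = hbv_markers,
                                     patterns = default_hbv_mode_table(),
                                     unlisted_policy = "intercept"))
  tibble(
    rule_id = sprintf("%06d", seq_along(defs)),
    analyte_code = map_chr(defs, "analyte_code"),
    category = map_chr(defs, "category"),
    params = map(defs, "params"),
    scope = map(defs, "scope")
  )
}

#' Simulation configuration
#'
#' Collects the knobs of the synthetic LIS stream: sizes, per-analyte
#' distributions, panel frequencies, pre-analytical fault rates and the
#' injected validation-error rates. All rates must lie in `[0, 1]` and
#' pattern frequencies must sum to 1.
#'
#' @param seed Master seed; every stream derives its own sub-seed from it.
#' @param n_patients,n_reports Stream sizes.
#' @param hbv_fraction Fraction of reports that are 5-marker HBV panels
#'   (the rest are 5-analyte chemistry reports).
#' @param qc_failure_rate,hemolysis_rate,lipemia_rate Per-test rates.
#' @param rule_fault_rate Fraction of rules corrupted by
#'   [inject_rule_faults()].
#' @param judge_error_rate Probability a simulated human judgment is
#'   flipped.
#' @param result_modification_rate Probability a green human release is a
#'   modified release.
#' @param reason_mix Named probabilities (a..e) of modification reasons;
#'   defaults follow the proportions observed in routine integrity
#'   validation data.
#' @param analyte_specs Per-analyte log-normal parameters.
#' @param hbv_frequencies HBV joint-pattern frequency table.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_patients = 200, n_reports = 1000,
                       hbv_fraction = 0.4,
                       qc_failure_rate = 0.01, hemolysis_rate = 0.02,
                       lipemia_rate = 0.01, rule_fault_rate = 0.06,
                       judge_error_rate = 0,
                       result_modification_rate = 0.02,
                       reason_mix = c(a = 0, b = 15 / 47, c = 18 / 47,
                                      d = 9 / 47, e = 5 / 47),
                       analyte_specs = default_analyte_specs(),
                       hbv_frequencies = default_hbv_frequencies()) {
  rates <- c(hbv_fraction, qc_failure_rate, hemolysis_rate, lipemia_rate,
             rule_fault_rate, judge_error_rate, result_modification_rate)
  if (any(!is.finite(rates)) || any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1]", class = "av_bad_config")
  }
  if (abs(sum(reason_mix) - 1) > 1e-9 && sum(reason_mix) != 0) {
    abort("reason_mix must sum to 1", class = "av_bad_config")
  }
  if (abs(sum(hbv_frequencies$prob) - 1) > 1e-9) {
    abort("hbv pattern frequencies must sum to 1", class = "av_bad_config")
  }
  structure(list(
    seed = seed, n_patients = n_patients, n_reports = n_reports,
    hbv_fraction = hbv_fraction, qc_failure_rate = qc_failure_rate,
    hemolysis_rate = hemolysis_rate, lipemia_rate = lipemia_rate,
    rule_fault_rate = rule_fault_rate, judge_error_rate = judge_error_rate,
    result_modification_rate = result_modification_rate,
    reason_mix = reason_mix, analyte_specs = analyte_specs,
    hbv_frequencies = hbv_frequencies
  ), class = "sim_config")
}

chem_analytes <- c("CRP", "ALB", "UREA", "HGB", "CORT")

#' Generate a synthetic LIS result stream
#'
#' Emulates the feed an autoverification engine sees: multi-analyte
#' reports (chemistry panels and HBV serology panels), per-patient result
#' histories for delta checks, QC failures and hemolysis/lipemia flags at
#' configured rates, and morning-biased cortisol draws. Deterministic for
#' a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List: `catalog` (tibble), `results` (tibble of test rows,
#'   grouped by barcode into reports), `history` (tibble).
#' @export
generate_stream <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "stream"), {
    n <- config$n_reports
    patients <- sprintf("P%04d", seq_len(config$n_patients))
    base <- av_time("2023-05-01 00:00")
    rows <- vector("list", n)
    hist_rows <- vector("list", n)
    is_hbv <- stats::runif(n) < config$hbv_fraction
    for (i in seq_len(n)) {
      bc <- sprintf("B%06d", i)
      pid <- sample(patients, 1)
      day <- sample(0:29, 1)
      if (is_hbv[i]) {
        hour_min <- 6 * 60 + sample(0:720, 1)
        freq <- config$hbv_frequencies
        k <- sample.int(nrow(freq), 1, prob = freq$prob)
        analytes <- hbv_markers
        values <- as.character(unlist(freq[k, hbv_markers]))
        units <- rep(NA_character_, 5)
        dsys <- "I2000SR"
      } else {
        # cortisol draws are morning-biased; the rest of the panel shares
        # the draw time
        hour_min <- if (stats::runif(1) < 0.9) {
          6 * 60 + 30 + sample(0:150, 1)
        } else {
          11 * 60 + sample(0:360, 1)
        }
        analytes <- chem_analytes
        values <- map_chr(analytes, function(a) {
          sp <- config$analyte_specs[[a]]
          format(round(stats::rlnorm(1, sp$meanlog, sp$sdlog), 2),
                 scientific = FALSE)
        })
        units <- c("mg/l", "g/l", "mmol/l", "g/l", "nmol/l")
        dsys <- "AU5800"
      }
      coll <- base + day * 86400 + hour_min * 60
      m <- length(analytes)
      flags <- character(m)
      hem <- stats::runif(m) < config$hemolysis_rate
      lip <- stats::runif(m) < config$lipemia_rate
      flags[hem] <- "hemolysis"
      flags[lip] <- ifelse(nzchar(flags[lip]), "hemolysis;lipemia", "lipemia")
      rows[[i]] <- tibble(
        barcode = bc, patient_id = pid, analyte_code = analytes,
        value = values, units = units,
        collection_time = coll, receipt_time = coll + 3600,
        qc_passed = stats::runif(m) >= config$qc_failure_rate,
        sample_flags = flags, detection_system = dsys,
        specimen_type = "serum"
      )
      if (!is_hbv[i]) {
        # a prior hemoglobin for the delta check: usually a small
        # physiological drift, occasionally a large jump
        v <- as.numeric(values[analytes == "HGB"])
        drift <- if (stats::runif(1) < 0.95) stats::runif(1, 0.92, 1.08)
        else stats::runif(1, 1.4, 1.8)
        hist_rows[[i]] <- tibble(
          patient_id = pid, analyte_code = "HGB",
          value = round(v * drift, 1),
          collection_time = coll - sample(1:6, 1) * 86400
        )
      }
    }
    list(catalog = default_catalog(),
         results = bind_rows(rows),
         history = bind_rows(hist_rows))
  })
}

#' Inject faults into rule definitions
#'
#' Corrupts a sampled subset of rule definitions the way real rule-entry
#' mistakes do: numeric thresholds off by a large factor (the rule never
#' fires), case-flipped categorical match text in combined-mode tables
#' (the pattern never matches lowercase instrument output), and a wrong
#' detection-system scope (the rule never applies). The returned manifest
#' is the ground truth that fault-recovery tests check against.
#'
#' @param rule_defs Tibble of rule definitions (see
#'   [default_rule_definitions()]).
#' @param rate Fault rate in `[0, 1]`.
#' @param seed RNG seed.
#' @return List: `rules` (possibly corrupted definitions), `manifest`
#'   (tibble `rule_id`, `fault_type`, `note`).
#' @export
inject_rule_faults <- function(rule_defs, rate, seed = 1) {
  if (!is_finite_num(rate) || rate < 0 || rate > 1) {
    abort("fault rate must lie in [0, 1]", class = "av_bad_config")
  }
  with_seed(derive_seed(seed, "faults"), {
    n <- nrow(rule_defs)
    hit <- which(stats::runif(n) < rate)
    manifest <- list()
    for (i in hit) {
      cat <- rule_defs$category[i]
      p <- validate_rule_params(cat, rule_defs$params[[i]])
      if (cat == "limit_range") {
        fld <- if (!is.null(p$intercept_above)) "intercept_above" else "intercept_below"
        p[[fld]] <- p[[fld]] * 100
        fault <- "threshold_off_by_large"
        note <- paste0(fld, " scaled x100; rule can no longer fire")
      } else if (cat == "delta_check") {
        p$threshold <- p$threshold * 100
        fault <- "threshold_off_by_large"
        note <- "delta threshold scaled x100"
      } else if (cat == "combined_mode") {
        pat <- p$patterns
        contra <- which(pat$flag == "contradictory")
        for (r in contra) {
          for (a in p$panel_analytes) {
            if (pat[[a]][r] == "positive") pat[[a]][r] <- "Positive"
          }
        }
        p$patterns <- pat
        fault <- "case_flip"
        note <- "match text 'positive' -> 'Positive'; pattern never matches"
      } else {
        rule_defs$scope[[i]] <- list(detection_systems = "GHOST-SYS")
        fault <- "wrong_scope"
        note <- "scoped to a detection system that does not exist"
      }
      rule_defs$params[[i]] <- p
      manifest[[length(manifest) + 1]] <-
        tibble(rule_id = rule_defs$rule_id[i], fault_type = fault, note = note)
    }
    empty <- tibble(rule_id = character(), fault_type = character(),
                    note = character())
    list(rules = rule_defs,
         manifest = if (length(manifest)) bind_rows(manifest) else empty)
  })
}

#' Simulate human correctness judgments
#'
#' Emulates staff judging each pending rule after seeing it execute:
#' faulted rules (per the manifest) are judged `system_error`, clean rules
#' `consistent`, and each judgment is flipped independently with
#' probability `judge_error_rate`.
#'
#' @param rule_defs Tibble of rule definitions under judgment.
#' @param manifest Fault manifest from [inject_rule_faults()].
#' @param judge_error_rate Flip probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param barcodes Optional report barcodes to attribute judgments to.
#' @return Tibble: `rule_id`, `barcode`, `judgment`, `failure_class`.
#' @export
simulate_judges <- function(rule_defs, manifest, judge_error_rate = 0,
                            seed = 1, barcodes = NULL) {
  if (!is_finite_num(judge_error_rate) || judge_error_rate < 0 ||
      judge_error_rate > 1) {
    abort("judge_error_rate must lie in [0, 1]", class = "av_bad_config")
  }
  with_seed(derive_seed(seed, "judges"), {
    n <- nrow(rule_defs)
    faulty <- rule_defs$rule_id %in% manifest$rule_id
    flip <- stats::runif(n) < judge_error_rate
    is_err <- xor(faulty, flip)
    tibble(
      rule_id = rule_defs$rule_id,
      barcode = barcodes %||% sprintf("JUDGE-%06d", seq_len(n)),
      judgment = ifelse(is_err, "system_error", "consistent"),
      failure_class = ifelse(is_err, "human_error", NA_character_)
    )
  })
}

#' Register a batch of rule definitions
#'
#' @param session A [lab_session()].
#' @param rule_defs Tibble of definitions (`rule_id`, `analyte_code`,
#'   `category`, `params`, optional `scope`).
#' @param now Registration timestamp.
#' @return The updated session.
#' @export
register_rules <- function(session, rule_defs, now = Sys.time()) {
  has_scope <- "scope" %in% names(rule_defs)
  for (i in seq_len(nrow(rule_defs))) {
    session <- register_rule(
      session, rule_defs$rule_id[i], rule_defs$analyte_code[i],
      rule_defs$category[i], rule_defs$params[[i]],
      scope = if (has_scope) rule_defs$scope[[i]] else NULL, now = now
    )
  }
  session
}

#' Apply a batch of recorded judgments
#'
#' @param session A [lab_session()].
#' @param judgments Tibble: `rule_id`, `barcode`, `judgment`, optional
#'   `failure_class`.
#' @param now Timestamp.
#' @return The updated session.
#' @export
apply_judgments <- function(session, judgments, now = Sys.time()) {
  has_fc <- "failure_class" %in% names(judgments)
  for (i in seq_len(nrow(judgments))) {
    fc <- if (has_fc && !is.na(judgments$failure_class[i])) {
      judgments$failure_class[i]
    } else NULL
    session <- record_judgment(session, judgments$rule_id[i],
                               judgments$barcode[i], judgments$judgment[i],
                               failure_class = fc, now = now)
  }
  session
}

# Allocate `total` among classes by largest remainder so deterministic
# class counts match target proportions exactly in total.
allocate_counts <- function(total, probs) {
  raw <- total * probs / sum(probs)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a full correctness-verification phase
#'
#' Drives the real lifecycle operations end to end at a configurable
#' scale: registers single-analyte limit rules, evaluates pending rules on
#' synthetic results (splitting executions between released and
#' intercepted outcomes), then records one human judgment per rule. All
#' counts flow through the audit log, from which
#' [summarize_correctness()] later derives its statistics.
#'
#' @param n_rules Number of rules registered.
#' @param n_error Number of rules judged `system_error` (the rest are
#'   judged `consistent`).
#' @param n_validations Number of pending-rule executions logged.
#' @param n_intercepted How many of those executions intercept their test.
#' @param failure_mix Named proportions of failure classes among error
#'   rules; defaults follow the observed correctness-failure taxonomy.
#' @param now Phase timestamp.
#' @return The resulting [lab_session()].
#' @export
simulate_correctness_phase <- function(n_rules = 833, n_error = 51,
                                       n_validations = 3814,
                                       n_intercepted = 1584,
                                       failure_mix = c(
                                         human_error = 0.633,
                                         specific_warning_target = 0.249,
                                         algorithm_code_error = 0.084,
                                         software_compatibility = 0.034),
                                       now = av_time("2023-06-01 08:00")) {
  stopifnot(n_error <= n_rules, n_intercepted <= n_validations)
  session <- lab_session()
  analytes <- sprintf("A%04d", seq_len(n_rules))
  ids <- sprintf("%06d", seq_len(n_rules))
  for (i in seq_len(n_rules)) {
    session <- register_rule(session, ids[i], analytes[i], "limit_range",
                             list(intercept_at_or_above = 5), now = now)
  }
  n_released <- n_validations - n_intercepted
  for (j in seq_len(n_validations)) {
    i <- ((j - 1) %% n_rules) + 1
    val <- if (j <= n_released) "1" else "9"
    rep <- as_report(tibble(
      barcode = sprintf("V%06d", j), patient_id = "P0001",
      analyte_code = analytes[i], value = val, qc_passed = TRUE,
      collection_time = now
    ))
    session <- session_evaluate(session, rep)
  }
  classes <- rep(names(failure_mix), allocate_counts(n_error, failure_mix))
  for (i in seq_len(n_rules)) {
    if (i <= n_rules - n_error) {
      session <- record_judgment(session, ids[i], sprintf("J%06d", i),
                                 "consistent", now = now)
    } else {
      session <- record_judgment(session, ids[i], sprintf("J%06d", i),
                                 "system_error",
                                 failure_class = classes[i - (n_rules - n_error)],
                                 now = now)
    }
  }
  session
}

#' Simulate integrity-phase modification events
#'
#' Drives [record_modification()] with a given tally of reasons on green
#' single-analyte reports, producing an audit log whose reason
#' distribution [summarize_integrity()] summarises.
#'
#' @param counts Named integer vector of modification counts per reason
#'   (`a`..`e`).
#' @param now Phase timestamp.
#' @return The resulting [lab_session()].
#' @export
simulate_integrity_reasons <- function(counts = c(a = 0, b = 15, c = 18,
                                                  d = 9, e = 5),
                                       now = av_time("2023-07-01 08:00")) {
  session <- lab_session()
  session <- register_rule(session, "000001", "CRP", "limit_range",
                           list(intercept_at_or_above = 5), now = now)
  session <- record_judgment(session, "000001", "SEED-1", "consistent",
                             now = now)
  session <- start_integrity(session, "CRP", target = 100, now = now)
  k <- 0
  for (r in names(counts)) {
    for (j in seq_len(counts[[r]])) {
      k <- k + 1
      rep <- as_report(tibble(
        barcode = sprintf("M%05d", k), patient_id = "P0001",
        analyte_code = "CRP", value = "1.0", qc_passed = TRUE,
        collection_time = now
      ))
      session <- record_modification(session, rep, "CRP", r,
                                     detail = paste("modification", k),
                                     now = now)
    }
  }
  session
}

#' Run a result stream through human release
#'
#' The integrity-validation workhorse: every report is evaluated; green
#' reports eligible for automated release are auto-released, other green
#' reports are released by hand — modified with the configured probability
#' and reason mix, unmodified otherwise — and red/purple reports are
#' intercepted. Deterministic for a fixed config seed.
#'
#' @param session A [lab_session()].
#' @param results Result-stream tibble (from [generate_stream()]).
#' @param config A [sim_config()] (supplies `result_modification_rate`,
#'   `reason_mix`, `seed`).
#' @return The updated session.
#' @export
run_release_stream <- function(session, results, config) {
  sp <- split_reports(results)
  with_seed(derive_seed(config$seed, "release"), {
    for (rep in sp$reports) {
      session <- process_report(session, rep,
                                now = rep$receipt_time[[1]] + 7200)
      disp <- attr(session, "disposition")
      if (disp$outcome == "manual_release_required") {
        if (stats::runif(1) < config$result_modification_rate) {
          reason <- sample(names(config$reason_mix), 1,
                           prob = config$reason_mix)
          session <- manual_release(
            session, rep, modified = TRUE,
            modification = list(analytes = rep$analyte_code[1],
                                reason = reason,
                                detail = "simulated result modification"),
            now = disp$timestamp
          )
        } else {
          session <- manual_release(session, rep, now = disp$timestamp)
        }
      }
    }
    session
  })
}
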