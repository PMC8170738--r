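test_that("limit, QC and abnormality rules intercept per their predicates", {
  lim <- list(id = "002009", category = "limit_range",
              params = validate_rule_params(
                "limit_range", list(intercept_at_or_above = 5)),
              status = "pending_verification")
  t_low <- list(barcode = "B1", analyte_code = "CRP", value = "1.8",
                qc_passed = TRUE, sample_flags = character())
  expect_false(evaluate_rule(lim, t_low)$triggered)
  t_edge <- t_low; t_edge$value <- "5.0"
  out <- evaluate_rule(lim, t_edge)
  expect_true(out$triggered)
  expect_match(out$message, "002009")

  qc <- list(id = "001879", category = "qc_check", params = list(),
             status = "verified")
  expect_false(evaluate_rule(qc, t_low)$triggered)
  t_fail <- t_low; t_fail$qc_passed <- FALSE
  expect_true(evaluate_rule(qc, t_fail)$triggered)

  ab <- list(id = "000003", category = "sample_abnormality",
             params = validate_rule_params("sample_abnormality",
                                           list(intercept_on = "hemolysis")),
             status = "verified")
  t_hem <- t_low; t_hem$sample_flags <- "hemolysis"
  expect_true(evaluate_rule(ab, t_hem)$triggered)
  expect_false(evaluate_rule(ab, t_low)$triggered)

  # non-numeric value under a numeric rule is a type error, not a pass
  t_cat <- t_low; t_cat$value <- "positive"
  expect_error(evaluate_rule(lim, t_cat), class = "av_type_mismatch")
})

test_that("sampling-time rules gate the collection clock time", {
  st <- list(id = "000004", category = "sampling_time_validity",
             params = validate_rule_params(
               "sampling_time_validity",
               list(window_start = "06:00", window_end = "10:00")),
             status = "verified")
  draw <- function(hhmm) {
    list(barcode = "B1", analyte_code = "CORT", value = "300",
         qc_passed = TRUE, sample_flags = character(),
         collection_time = as.POSIXct(paste("2023-05-10", hhmm), tz = "UTC"))
  }
  expect_false(evaluate_rule(st, draw("08:00"))$triggered)
  expect_true(evaluate_rule(st, draw("14:00"))$triggered)
  expect_false(evaluate_rule(st, draw("06:00"))$triggered)
  expect_false(evaluate_rule(st, draw("10:00"))$triggered)
})

test_that("delta check compares against the prior value in the window", {
  h <- tibble::tibble(patient_id = "P1", analyte_code = "HGB",
                      value = 50, collection_time = T0 - 2 * 86400)
  mk <- function(v) list(patient_id = "P1", analyte_code = "HGB",
                         value = as.character(v), collection_time = T0,
                         qc_passed = TRUE, sample_flags = character())
  # identity: zero change never triggers
  h10 <- h; h10$value <- 10
  expect_false(check_delta(list(mode = "percent", threshold = 20),
                           mk(10), h10)$triggered)
  # |100-50|/50*100 = 100% > 50%
  expect_true(check_delta(list(mode = "percent", threshold = 50),
                          mk(100), h)$triggered)
  # no prior in window, stated default does not trigger
  expect_false(check_delta(list(mode = "percent", threshold = 20),
                           mk(7), h[0, ])$triggered)
  expect_true(check_delta(list(mode = "percent", threshold = 20,
                               trigger_when_no_history = TRUE),
                          mk(7), h[0, ])$triggered)
  # zero prior falls back to an absolute comparison
  h0 <- h; h0$value <- 0
  expect_true(check_delta(list(mode = "percent", threshold = 20),
                          mk(30), h0)$triggered)
  expect_false(check_delta(list(mode = "percent", threshold = 20),
                           mk(10), h0)$triggered)
})

test_that("combined mode matches the joint HBV pattern case-sensitively", {
  markers <- c("HBsAg", "HBsAb", "HBeAg", "HBeAb", "HBcAb")
  tab <- rbind(
    data.frame(HBsAg = "positive", HBsAb = "positive", HBeAg = "negative",
               HBeAb = "negative", HBcAb = "negative", flag = "contradictory"),
    data.frame(HBsAg = "negative", HBsAb = "positive", HBeAg = "negative",
               HBeAb = "negative", HBcAb = "negative", flag = "allowed")
  )
  params <- list(panel_analytes = markers, patterns = tab)
  contra <- hbv_panel_report("H1", c("positive", "positive", "negative",
                                     "negative", "negative"))
  expect_true(check_combined_mode(params, contra)$triggered)
  vacc <- hbv_panel_report("H2", c("negative", "positive", "negative",
                                   "negative", "negative"))
  expect_false(check_combined_mode(params, vacc)$triggered)
  # unlisted pattern: policy decides
  neg <- hbv_panel_report("H3", rep("negative", 5))
  expect_true(check_combined_mode(params, neg)$triggered)
  params$unlisted_policy <- "pass"
  expect_false(check_combined_mode(params, neg)$triggered)
  # missing panel member named in the error
  expect_error(check_combined_mode(params, contra[1:4, ]),
               regexp = "HBcAb", class = "av_missing_panel_member")
})

test_that("the worked CRP example colours purple, then green, and red at 5", {
  s <- crp_session()
  rep_18 <- one_test_report("B100", value = "1.8")
  w <- evaluate_report(s, rep_18)
  expect_equal(w$barcode_color, "purple")
  expect_false(any(w$outcomes$triggered))

  s_ver <- record_judgment(s, "002009", "B100", "consistent", now = T0)
  expect_equal(evaluate_report(s_ver, rep_18)$barcode_color, "green")

  w_red <- evaluate_report(s_ver, one_test_report("B101", value = "9.0"))
  expect_equal(w_red$barcode_color, "red")
  expect_match(w_red$outcomes$message[w_red$outcomes$triggered], "002009")
})

test_that("a test with no applicable rule is red, never silently green", {
  s <- crp_session()
  w <- evaluate_report(s, one_test_report("B1", analyte = "UNRULED",
                                          value = "1"))
  expect_equal(w$barcode_color, "red")
  # scope restriction makes a rule inapplicable
  s2 <- lab_session() |>
    register_rule("000001", "ALB", "sample_abnormality",
                  list(intercept_on = "hemolysis"),
                  scope = list(detection_systems = "AU5800"), now = T0)
  w2 <- evaluate_report(s2, one_test_report("B2", analyte = "ALB",
                                            value = "40", flags = "hemolysis",
                                            dsys = "OTHER"))
  expect_equal(w2$barcode_color, "red")  # zero applicable rules -> fail safe
  w3 <- evaluate_report(s2, one_test_report("B3", analyte = "ALB",
                                            value = "40", flags = "hemolysis",
                                            dsys = "AU5800"))
  expect_true(any(w3$outcomes$triggered))
})

test_that("barcode colour is the stated pure function of test colours", {
  # three analytes, one rule each, arranged to produce any colour per test
  mk_session <- function(colors) {
    s <- lab_session()
    for (i in 1:3) {
      a <- paste0("AN", i)
      s <- register_rule(s, sprintf("%06d", i), a, "limit_range",
                         list(intercept_at_or_above = 5), now = T0)
      if (colors[i] != "purple") {
        s <- record_judgment(s, sprintf("%06d", i), paste0("S", i),
                             "consistent", now = T0)
      }
    }
    s
  }
  combos <- expand.grid(c1 = c("green", "red", "purple"),
                        c2 = c("green", "red", "purple"),
                        c3 = c("green", "red", "purple"),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(combos))) {
    cols <- unlist(combos[k, ])
    s <- mk_session(cols)
    rep <- as_report(tibble::tibble(
      barcode = "B1", patient_id = "P1",
      analyte_code = paste0("AN", 1:3),
      value = ifelse(cols == "red", "9", "1"),
      qc_passed = TRUE, collection_time = T0
    ))
    w <- evaluate_report(s, rep)
    expect_equal(w$tests$color, unname(cols))
    want <- if (any(cols == "red")) "red"
    else if (all(cols == "green")) "green" else "purple"
    expect_equal(w$barcode_color, want)
  }
})

test_that("engine outcomes equal brute-force predicates on random cases", {
  set.seed(97)
  n <- 1000
  for (k in seq_len(n)) {
    v <- round(stats::runif(1, 0, 10), 2)
    above <- if (stats::runif(1) < 0.7) round(stats::runif(1, 0, 10), 2) else NULL
    below <- if (is.null(above) || stats::runif(1) < 0.3)
      round(stats::runif(1, 0, 5), 2) else NULL
    ai <- stats::runif(1) < 0.5
    bi <- stats::runif(1) < 0.5
    params <- list(intercept_above = above, intercept_below = below,
                   above_inclusive = ai, below_inclusive = bi)
    params <- params[!vapply(params, is.null, logical(1))]
    rule <- list(id = "999999", category = "limit_range",
                 params = validate_rule_params("limit_range", params),
                 status = "verified")
    t <- list(barcode = "B", analyte_code = "X", value = as.character(v),
              qc_passed = TRUE, sample_flags = character())
    expect_equal(evaluate_rule(rule, t)$triggered,
                 oracle_limit(v, above, below, ai, bi))
  }
})

test_that("delta engine agrees with its oracle over random histories", {
  set.seed(98)
  for (k in 1:1000) {
    v <- round(stats::runif(1, 0, 100), 1)
    np <- sample(0:3, 1)
    pv <- round(stats::runif(np, 0, 100), 1)
    if (np > 0 && stats::runif(1) < 0.2) pv[1] <- 0
    pt <- T0 - stats::runif(np, -1, 10) * 86400
    mode <- sample(c("percent", "absolute"), 1)
    th <- round(stats::runif(1, 0, 60), 1)
    lb <- sample(c(2, 7), 1)
    tnh <- stats::runif(1) < 0.5
    h <- tibble::tibble(patient_id = rep("P1", np), analyte_code = rep("X", np),
                        value = pv, collection_time = pt)
    got <- check_delta(list(mode = mode, threshold = th, lookback_days = lb,
                            trigger_when_no_history = tnh),
                       list(patient_id = "P1", analyte_code = "X",
                            value = as.character(v), collection_time = T0,
                            qc_passed = TRUE, sample_flags = character()),
                       h)$triggered
    expect_equal(got, oracle_delta(v, pv, pt, T0, lb, mode, th, th, tnh))
  }
})

test_that("sampling, abnormality, QC and combined engines match their oracles", {
  set.seed(99)
  for (k in 1:1000) {
    # sampling time (windows may wrap midnight)
    sm <- sample(0:1439, 1); em <- sample(0:1439, 1); mm <- sample(0:1439, 1)
    pr <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)
    st <- list(id = "1", category = "sampling_time_validity",
               params = validate_rule_params("sampling_time_validity",
                                             list(window_start = pr(sm),
                                                  window_end = pr(em))),
               status = "verified")
    t <- list(barcode = "B", analyte_code = "X", value = "1", qc_passed = TRUE,
              sample_flags = character(),
              collection_time = as.POSIXct("2023-05-10", tz = "UTC") + mm * 60)
    expect_equal(evaluate_rule(st, t)$triggered, oracle_sampling(mm, sm, em))

    # abnormality
    flags <- sample(c("hemolysis", "lipemia"), sample(0:2, 1))
    on <- sample(c("hemolysis", "lipemia"), sample(1:2, 1))
    ab <- list(id = "2", category = "sample_abnormality",
               params = list(intercept_on = on), status = "verified")
    t$sample_flags <- flags
    expect_equal(evaluate_rule(ab, t)$triggered, oracle_abnormality(flags, on))

    # qc
    qcp <- stats::runif(1) < 0.5
    qc <- list(id = "3", category = "qc_check", params = list(),
               status = "verified")
    t$qc_passed <- qcp
    expect_equal(evaluate_rule(qc, t)$triggered, oracle_qc(qcp))

    # combined mode over a random 2-marker table
    vals <- sample(c("positive", "negative"), 2, replace = TRUE)
    nrow_tab <- sample(1:4, 1)
    rows <- replicate(nrow_tab,
                      sample(c("positive", "negative"), 2, replace = TRUE),
                      simplify = FALSE)
    flags_tab <- sample(c("contradictory", "allowed"), nrow_tab,
                        replace = TRUE)
    pol <- sample(c("pass", "intercept"), 1)
    tab <- do.call(rbind, lapply(rows, function(r) {
      data.frame(M1 = r[1], M2 = r[2])
    }))
    tab$flag <- flags_tab
    panel <- tibble::tibble(analyte_code = c("M1", "M2"), value = vals)
    got <- check_combined_mode(list(panel_analytes = c("M1", "M2"),
                                    patterns = tab, unlisted_policy = pol),
                               panel)$triggered
    # oracle matches first row; mirror duplicate-row semantics by keeping
    # the first match
    expect_equal(got, oracle_combined(vals, rows, flags_tab, pol))
  }
})

test_that("warnings are deterministic and colour-monotone under rule changes", {
  s <- crp_session()
  rep <- one_test_report("B1", value = "1.8")
  w1 <- jsonlite::serializeJSON(evaluate_report(s, rep))
  w2 <- jsonlite::serializeJSON(evaluate_report(s, rep))
  expect_identical(w1, w2)

  # adding a non-triggering verified rule never turns green into red
  s_ver <- record_judgment(s, "002009", "B100", "consistent", now = T0)
  expect_equal(evaluate_report(s_ver, rep)$barcode_color, "green")
  s_more <- s_ver |>
    register_rule("003000", "CRP", "limit_range",
                  list(intercept_at_or_above = 100), now = T0) |>
    record_judgment("003000", "B200", "consistent", now = T0)
  expect_equal(evaluate_report(s_more, rep)$barcode_color, "green")

  # deleting a rule never turns green into red
  s_del <- record_judgment(
    register_rule(s_more, "003001", "CRP", "qc_check", now = T0),
    "003001", "B201", "system_error", failure_class = "human_error", now = T0)
  expect_equal(evaluate_report(s_del, rep)$barcode_color, "green")
})
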