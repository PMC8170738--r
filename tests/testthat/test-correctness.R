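test_that("registration stores pending rules atomically and audits them", {
  s <- lab_session() |>
    register_rule("002009", "CRP", "limit_range",
                  list(intercept_at_or_above = 5), now = T0)
  expect_equal(rules(s)$status, "pending_verification")
  expect_equal(audit_log(s)$kind, "rule_registered")

  expect_error(register_rule(s, "002009", "CRP", "qc_check"),
               class = "av_duplicate_rule")
  expect_error(register_rule(s, "2009", "CRP", "qc_check"),
               class = "av_bad_input")
  # invalid params store nothing
  s_try <- tryCatch(register_rule(s, "002010", "CRP", "limit_range", list()),
                    error = function(e) s)
  expect_identical(rules(s_try), rules(s))
})

test_that("judgments drive the lifecycle and refuse duplicates", {
  s <- lab_session() |>
    register_rule("002009", "CRP", "limit_range",
                  list(intercept_at_or_above = 5), now = T0)
  s_ok <- record_judgment(s, "002009", "B100", "consistent", now = T0)
  expect_equal(rules(s_ok)$status, "verified")

  s_bad <- record_judgment(s, "002009", "B100", "system_error",
                           failure_class = "human_error", now = T0)
  expect_equal(rules(s_bad)$status, "deleted")
  expect_equal(rules(s_bad)$failure_class, "human_error")

  expect_error(record_judgment(s_bad, "002009", "B101", "consistent"),
               class = "av_bad_transition")
  expect_error(record_judgment(s_ok, "002009", "B101", "consistent"),
               class = "av_bad_transition")
  expect_error(record_judgment(s, "999999", "B1", "consistent"),
               class = "av_no_such_rule")
  # one judgment per (rule, report)
  s2 <- lab_session(confirmations_required = 2) |>
    register_rule("000001", "CRP", "qc_check", now = T0) |>
    record_judgment("000001", "B1", "consistent", now = T0)
  expect_error(record_judgment(s2, "000001", "B1", "consistent"),
               class = "av_duplicate_judgment")
  s2 <- record_judgment(s2, "000001", "B2", "consistent", now = T0)
  expect_equal(rules(s2)$status, "verified")
})

test_that("pending rules expire strictly after the verification window", {
  s <- lab_session() |>
    register_rule("000001", "CRP", "qc_check", now = T0) |>
    register_rule("000002", "ALB", "qc_check", now = T0) |>
    record_judgment("000002", "B1", "consistent", now = T0)

  s10 <- expire_pending(s, now = T0 + 10 * 86400)
  expect_equal(attr(s10, "expired_ids"), character())

  s11 <- expire_pending(s, now = T0 + 11 * 86400)
  expect_equal(attr(s11, "expired_ids"), "000001")
  r <- rules(s11)
  expect_equal(r$status[r$rule_id == "000001"], "deleted")
  expect_equal(r$failure_class[r$rule_id == "000001"], "expired")
  expect_equal(r$status[r$rule_id == "000002"], "verified")

  # idempotent at the same clock
  s11b <- expire_pending(s11, now = T0 + 11 * 86400)
  expect_equal(attr(s11b, "expired_ids"), character())
  expect_identical(rules(s11b), rules(s11))
})

test_that("rules are immutable: modification always fails and changes nothing", {
  s <- verified_session()
  before <- rules(s)
  expect_error(modify_rule(s, "000001", list(intercept_at_or_above = 50)),
               class = "av_modification_forbidden")
  sp <- lab_session() |> register_rule("000009", "CRP", "qc_check", now = T0)
  expect_error(modify_rule(sp, "000009"),
               class = "av_modification_forbidden")
  expect_identical(rules(s), before)
})

test_that("a project is verified only when every live rule is verified", {
  s <- lab_session() |>
    register_rule("000001", "CRP", "qc_check", now = T0) |>
    register_rule("000002", "CRP", "limit_range",
                  list(intercept_at_or_above = 5), now = T0)
  s1 <- record_judgment(s, "000001", "B1", "consistent", now = T0)
  expect_false(is_project_verified(s1, "CRP"))
  s2 <- record_judgment(s1, "000002", "B2", "consistent", now = T0)
  expect_true(is_project_verified(s2, "CRP"))
  # deleted rules do not block
  s3 <- record_judgment(s, "000001", "B1", "consistent", now = T0) |>
    record_judgment("000002", "B2", "system_error",
                    failure_class = "human_error", now = T0)
  expect_true(is_project_verified(s3, "CRP"))
  # all rules deleted: nothing left to validate
  s4 <- record_judgment(s, "000001", "B1", "system_error", now = T0) |>
    record_judgment("000002", "B2", "system_error", now = T0)
  expect_error(is_project_verified(s4, "CRP"), class = "av_no_rules")
  expect_error(is_project_verified(s, "NOPE"), class = "av_no_rules")
})

test_that("a rule that ever failed can never become verified", {
  # exhaustive over all judgment/expiry action sequences of length <= 4
  actions <- c("ok", "err", "expire_now", "expire_late")
  base <- lab_session(confirmations_required = 2) |>
    register_rule("000001", "CRP", "qc_check", now = T0)
  check_node <- function(s, had_err, depth, bc) {
    r <- rules(s)
    if (had_err) expect_false(r$status == "verified")
    if (depth == 4) return(invisible())
    for (a in actions) {
      res <- tryCatch(switch(a,
        ok = record_judgment(s, "000001", paste0("B", bc), "consistent",
                             now = T0),
        err = record_judgment(s, "000001", paste0("B", bc), "system_error",
                              failure_class = "human_error", now = T0),
        expire_now = expire_pending(s, now = T0),
        expire_late = expire_pending(s, now = T0 + 11 * 86400)
      ), error = function(e) NULL)
      if (is.null(res)) next
      check_node(res, had_err || a == "err", depth + 1, bc + 1)
    }
  }
  check_node(base, FALSE, 0, 1)
})

test_that("rule counts are conserved across any operation sequence", {
  set.seed(11)
  s <- lab_session()
  n_reg <- 0
  for (i in 1:60) {
    op <- sample(c("reg", "ok", "err", "expire"), 1)
    id <- sprintf("%06d", i)
    s <- tryCatch(switch(op,
      reg = { n_reg <- n_reg + 1; register_rule(s, id, "CRP", "qc_check",
                                                now = T0) },
      ok = record_judgment(s, sample(names(s$rules), 1), paste0("B", i),
                           "consistent", now = T0),
      err = record_judgment(s, sample(names(s$rules), 1), paste0("B", i),
                            "system_error", now = T0),
      expire = expire_pending(s, now = T0 + sample(0:12, 1) * 86400)
    ), error = function(e) s)
    r <- rules(s)
    expect_equal(nrow(r),
                 sum(r$status == "pending_verification") +
                   sum(r$status == "verified") + sum(r$status == "deleted"))
  }
  expect_equal(nrow(rules(s)), n_reg)
})

test_that("with fault rate e and perfect judges, about 1 - e of rules verify", {
  n <- 1000
  e <- 0.1
  defs <- tibble::tibble(
    rule_id = sprintf("%06d", 1:n),
    analyte_code = sprintf("A%04d", 1:n),
    category = "limit_range",
    params = replicate(n, list(intercept_at_or_above = 5), simplify = FALSE),
    scope = vector("list", n)
  )
  f <- inject_rule_faults(defs, e, seed = 123)
  s <- lab_session() |>
    register_rules(f$rules, now = T0) |>
    apply_judgments(simulate_judges(f$rules, f$manifest, 0, seed = 123),
                    now = T0)
  frac <- mean(rules(s)$status == "verified")
  sigma <- sqrt(e * (1 - e) / n)
  expect_lt(abs(frac - (1 - e)), 3 * sigma + 1e-12)
})
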