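# autoverifyr

Autoverification — releasing clinical laboratory reports by software,
without per-report human review — is only as safe as the validation of its
warning rules. `autoverifyr` implements a complete, auditable validation
workflow for an autoverification engine, aimed at laboratory
informaticians and LIS/middleware developers who need to prove that
programmed release logic behaves as intended before switching it on.

The package separates the two stages of autoverification and attaches one
validation phase to each:

* **Automatic warning** evaluates every applicable rule for every test and
  colours it: *red* if any rule intercepts (limit range, delta check,
  combined-mode panel consistency, sampling-time validity, hemolysis or
  lipemia flags, QC gate), *purple* if nothing intercepts but an
  applicable rule is still pending human confirmation, *green* otherwise.
  A report's barcode is green iff all its tests are green, red if any test
  is red, purple in between.
* **Correctness verification** (phase 1, per rule): a newly registered
  rule is `pending_verification`; staff who watch it execute record a
  judgment. Consistent ⇒ `verified`; system error ⇒ `deleted` (terminal).
  Guards: rules are immutable, a rule that ever failed can never verify,
  and pending rules auto-delete after 10 days.
* **Integrity validation** (phase 2, per analyte): once all an analyte's
  live rules are verified, a counter `n` tracks unmodified human releases
  of green reports toward a target `T` (e.g. 3000). A modified release
  demands a reason; reasons that indict the rule set (execution error,
  bad setting, missing rule) reset `n` to 0 and stop automated reporting.
  A report auto-releases only when the master switch is on, its warning is
  green, and every analyte on it has `n ≥ T`.

Every decision appends to a gapless, append-only audit log;
summary statistics (`summarize_correctness()`, `summarize_integrity()`)
and counter state (`replay_counters()`) are pure functions of that log.
A seedable synthetic-LIS module (`sim_config()`, `generate_stream()`,
`inject_rule_faults()`, `simulate_judges()`) generates multi-analyte
streams — including 5-marker HBV serology panels — with configurable QC,
specimen-flag, fault and judge-error rates, so the whole pipeline is
testable end to end with no external data.

## Worked example

The canonical C-reactive protein scenario: a verified QC rule (`001879`)
and a pending limit rule (`002009`, "intercept results ≥ 5 mg/l") applied
to a CRP of 1.8 mg/l that passed QC.

```r
library(autoverifyr)
library(tibble)

t0 <- as.POSIXct("2023-05-10 08:00:00", tz = "UTC")
s <- lab_session() |>
  register_rule("001879", "CRP", "qc_check", now = t0 - 86400) |>
  record_judgment("001879", "SEED", "consistent", now = t0 - 86400) |>
  register_rule("002009", "CRP", "limit_range",
                list(intercept_at_or_above = 5, units = "mg/l"), now = t0)

rep <- as_report(tibble(barcode = "B100", patient_id = "P0001",
                        analyte_code = "CRP", value = "1.8", units = "mg/l",
                        collection_time = t0, qc_passed = TRUE))
evaluate_report(s, rep)
#> <report warning> barcode B100 -> purple
#> # A tibble: 1 × 4
#>   analyte_code color  n_triggered n_pending
#>   <chr>        <chr>        <int>     <int>
#> 1 CRP          purple           0         1
```

Purple: no rule intercepts, but `002009` awaits confirmation. The
technician confirms the execution was consistent, which verifies the rule;
the same report is now green, and a CRP of 9.0 is intercepted with its
cause:

```r
s <- record_judgment(s, "002009", "B100", "consistent", now = t0)
evaluate_report(s, rep)$barcode_color
#> [1] "green"

red <- as_report(tibble(barcode = "B101", patient_id = "P0001",
                        analyte_code = "CRP", value = "9.0", units = "mg/l",
                        collection_time = t0, qc_passed = TRUE))
w <- evaluate_report(s, red)
w$barcode_color
#> [1] "red"
w$outcomes$message[w$outcomes$triggered]
#> [1] "rule 002009 (limit_range): result 9 >= 5"
```

Phase statistics come straight from an audit log. Driving the full
correctness lifecycle at reference scale (833 rules, one judgment each,
3814 logged pending-rule executions):

```r
summarize_correctness(simulate_correctness_phase())
#> Correctness verification
#>   rules: 833 registered, 782 verified (93.88%), 51 deleted, 0 pending
#>   validations: 3814 (58.47% released, 41.53% intercepted)
#>   ...
```

93.88% of rules verified; 58.47% of validations released the test and
41.53% intercepted it — computed at 2 decimals with half-up rounding from
the event counts alone.

A command-line pipeline (`simulate`, `init-rules`, `evaluate`, `verify`,
`release`, `metrics`) is installed at `inst/cli/autoverify.R`; run it with
`Rscript` against JSON/CSV/JSONL files (schema in
`inst/extdata/rules-schema.json`).

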