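---
title: "Validating laboratory autoverification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating laboratory autoverification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoverifyr)
```

## The problem

Clinical laboratories release enormous numbers of test reports, and
autoverification — software that checks each result against programmed
warning rules and releases unremarkable reports without a human — is the
standard way to keep turnaround times short. The risk is concentrated in
one question: *do the programmed rules actually behave the way the person
who wrote them intended, and do they cover everything a human reviewer
would have caught?* Classical validation answers this with a large manual
campaign: staff review thousands of reports in parallel with the machine,
record agreement by hand, and tabulate the results afterwards. That is
slow, subjective, and — worse — skippable.

`autoverifyr` implements the alternative this package is built around:
validation as a property of the system itself, recorded in an append-only
audit log while staff do their ordinary work. It separates two stages with
two different validation questions:

* **Automatic warning** colours each test and each report barcode. A test
  is *red* when any applicable rule intercepts it (with the cause shown),
  *purple* when nothing intercepts it but at least one applicable rule is
  still awaiting human confirmation, and *green* otherwise. The barcode is
  green only if every test is green, red if any test is red, purple in
  between. Warning only judges; it never releases.
* **Automated reporting** releases a green-barcode report with no human
  action — but only for analytes that have completed both validation
  phases, and only while the laboratory-wide master switch is on.

The two validation phases map onto these stages:

1. **Correctness verification** (per rule). A newly registered rule is
   labelled `pending_verification`. When staff review a report on which
   the pending rule executed, they record whether the machine's behaviour
   matched their own judgment. A consistent judgment verifies the rule; a
   system-error judgment deletes it. Four guards make this safe: a pending
   rule not verified within 10 days is deleted automatically; rules are
   immutable (the only edit is delete-and-re-register, which restarts
   verification); a rule that ever failed can never be converted to
   verified; and deletion is terminal.
2. **Integrity validation** (per analyte, or "project"). Once *all* of an
   analyte's live rules are verified, a validation counter starts toward a
   laboratory-chosen target (for example 3000 reports). Every time a human
   releases a green report *without modifying anything*, each of the
   report's analytes' counters increases by one — a human has certified
   the machine's judgment once. If the reviewer modifies a result, the
   system demands a reason: (a) rule execution error, (b) inappropriate
   rule setting, (c) a new rule is needed, (d) unrelated to
   autoverification, (e) the warning itself prompted the fix. Reasons a–c
   indict the rule set, so the named analytes' counters are cleared to
   zero and automated reporting stops for them; d–e leave counters
   untouched. When every analyte on a report has reached its target,
   the report is released automatically.

## State and purity

All mutable state lives in a `lab_session()` object threaded through the
verbs (`register_rule()`, `record_judgment()`, `record_release()`,
`process_report()`, ...), each of which returns the updated session, so a
validation run composes with the native pipe. Every decision appends an
event to the session's audit log; the log is append-only, gaplessly
numbered, and sufficient: `summarize_correctness()`,
`summarize_integrity()` and `replay_counters()` are pure functions of the
log, and replaying a session's log reconstructs its counter states
exactly. This event-sourcing discipline is what makes the validation
statistics trustworthy — nothing is counted that did not happen through an
operation.

## Rule categories and their parameters

Six rule categories are built in (a registry hook accepts more; middleware
deployments typically carry additional, site-specific categories that are
not specified enough to standardise):

| category | parameters (defaults) | intercepts when |
|---|---|---|
| `limit_range` | `intercept_above`/`intercept_below`, inclusivity flags (inclusive) | result beyond a bound |
| `delta_check` | `mode` (percent), `threshold`, `lookback_days` (7), `trigger_when_no_history` (FALSE), `zero_fallback` (= threshold) | change vs the latest prior result in the window exceeds the threshold |
| `combined_mode` | `panel_analytes`, `patterns` table, `unlisted_policy` (intercept) | the panel's joint qualitative pattern is flagged contradictory, or is unlisted under the intercept policy |
| `sampling_time_validity` | `window_start`, `window_end` ("HH:MM") | collection clock time outside the window (windows may wrap midnight) |
| `sample_abnormality` | `intercept_on` ⊆ {hemolysis, lipemia} | a named specimen flag is present |
| `qc_check` | none | the analytical run's QC did not pass |

Every limit carries an explicit inclusivity flag because rule text like
"greater than or equal to 5" must be reproduced exactly; the default is
inclusive. A rule may carry a scope restricting it to named detection
systems and/or specimen types; out-of-scope tests are simply not covered
by it.

Numeric and categorical handling: values travel as strings (one stream
carries both 1.8 mg/L and "positive"); numeric categories parse the value
and raise a type error — never a silent pass — on non-numeric input.
Categorical matching is **case-sensitive**: a mis-cased pattern
("Positive" against instrument output "positive") is exactly the kind of
entry error correctness verification exists to catch, so the engine must
not smooth over it. The same strictness applies to category names at load
time.

## Decisions taken where the design was open

* **Purple semantics.** Purple marks "a pending rule is involved and a
  human must confirm", not interception: a test is purple when no rule
  triggers but at least one applicable rule is pending. Red always wins.
* **Zero applicable rules → red.** A test no rule covers is routed to
  manual review. Fail-safe: nothing auto-passes unruled.
* **Percent delta against a prior of zero.** No ratio exists, so the
  comparison falls back to an absolute check against `zero_fallback`
  (default: the percent threshold reinterpreted in result units). The
  check stays live instead of dividing by zero or silently passing.
* **Unlisted combined-mode patterns intercept by default.** Silent passes
  of uncovered panel scenarios are the observed failure mode of mode
  tables; a laboratory that wants permissive behaviour opts into
  `unlisted_policy = "pass"` per rule.
* **Expiry boundary.** "Within 10 days" is read as the allowed window: a
  rule pending exactly 10 days is retained, strictly older is deleted.
  Both readings of the guard (delete on failure, delete on timeout) are
  implemented — explicit failures delete immediately, timeouts sweep the
  rest.
* **One judgment per (rule, report).** Repeated confirmations require
  distinct specimens, so a single sample can never certify a rule twice.
  One consistent judgment verifies by default; `confirmations_required`
  raises the bar.
* **Counter clearing scope.** A reason-a/b/c modification clears the
  counters of the analytes named in the modification event, not every
  analyte on the report ("the related items").
* **Automated releases do not increment counters.** The counter measures
  *human-certified* agreement; once automated release is running,
  validation for that analyte is complete. This also makes the gating
  arithmetic crisp: with target *T* and no modifications, a counter stops
  at exactly *T* because the next green report releases automatically.
* **Release threshold is inclusive** (`count >= target`): the target is a
  goal to reach, and the recorded progress screens show counts strictly
  below target as blocked.
* **Validations vs judgments.** The correctness statistics count
  *validations* as pending-rule executions shown to staff
  (`rule_evaluated` events) — a rule is typically watched several times —
  while status changes flow from the (fewer) judgment events. The two
  event kinds are deliberately distinct in the log.

## The synthetic LIS stream

No deposited laboratory dataset accompanies this problem, so the package
carries a seedable generator (`sim_config()`, `generate_stream()`)
emulating the feed an engine sees in production: 5-analyte chemistry
reports (CRP, albumin, urea, hemoglobin, cortisol) and 5-marker HBV
serology panels; per-patient hemoglobin histories for delta checks; QC
failures and hemolysis/lipemia flags at configured per-test rates
(defaults 1%, 2%, 1%); morning-biased cortisol draws with 10% of
collections outside the 06:00–10:00 window. Quantitative results are
log-normal around mid-reference-range (no distributional ground truth
exists; the parameters are configuration, not claims), and HBV panels are
drawn from a joint pattern table concentrated on common serostatus
patterns, with the contradictory HBsAg+/HBsAb+ pattern at probability
zero. Fault injection (`inject_rule_faults()`) corrupts rule definitions
the way real entry errors do — thresholds off by a large factor,
case-flipped match text, wrong detection-system scope — and returns a
ground-truth manifest; `simulate_judges()` emulates staff with a
configurable error rate. Default fault and modification rates (6% rule
faults, 2% modified releases) sit at the scale of the validation
campaigns the workflow was designed around.

What the generator does **not** emulate — pathophysiology, instrument
drift, turnaround-time structure, demographic covariates, correlated
multi-analyte failures — bounds what passing tests show: they demonstrate
that the engine, lifecycle and gating behave exactly as specified on
streams with realistic shapes and rates, not that any particular
laboratory's rule set is clinically adequate.

## Verification approach and problem sizes

The test suite checks every predicate against independent straight-line
oracles on 1000 random cases per category, and checks `history_lookup()`
against a brute-force scan. Lifecycle safety is model-checked: all event
sequences of the one-analyte system to depth 6 are explored (memoised on
the small state signature, so equivalent states are expanded once), and at
every release the safety conditions — switch on, green warning, verified
rule, counter at target — are re-derived from the pre-release state rather
than trusted from the engine. Phase statistics are exercised at the
reference scale (833 rules, 3814 validations; reason tally a:0, b:15,
c:18, d:9, e:5) and fault recovery on streams of 1000 reports with a
per-analyte target of 200; these sizes keep the complete suite
comfortably inside a few minutes on one core while leaving the arithmetic
non-trivial. Percentages use half-up rounding (2 decimals for correctness
statistics, 1 for reason distributions) to match laboratory reporting
conventions; note the ten-step workload model's printed totals
(452 h / 275 h) differ from their own column sums (451 h / 275.25 h),
which `workload_compare()` reports as a flagged discrepancy rather than
resolving silently.

```{r example}
s <- simulate_correctness_phase(n_rules = 20, n_error = 3,
                                n_validations = 60, n_intercepted = 24)
summarize_correctness(s)
```

## Limitations

* The package validates *behaviour against intent*, not clinical
  appropriateness of any rule; reference intervals, Westgard QC internals
  and patient-based QC are consumed as boolean inputs or parameters.
* Timestamps are timezone-naive wall-clock times in a single configured
  laboratory timezone; multi-site deployments would need explicit zones.
* The correctness failure taxonomy is metadata for analysis, not control
  flow; repairing algorithm defects is a developer activity outside the
  package.
* Periodic revalidation scheduling is representable (re-run
  `start_integrity()`) but not automated.
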