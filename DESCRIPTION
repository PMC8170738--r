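Package: autoverifyr
Title: Validation of Laboratory Autoverification Rules and Automated Report Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A laboratory-information-system style autoverification engine
    together with the two-phase validation workflow used to bring it safely
    into production. Warning rules (limit range, delta check, combined mode,
    sampling-time validity, sample abnormality, quality control) colour tests
    and report barcodes green, red or purple; newly registered rules pass
    through a human-in-the-loop correctness-verification lifecycle, and
    per-analyte integrity counters of unmodified human releases gate the
    switch to fully automated report release. Includes an append-only audit
    log with event-sourced replay, summary statistics of both validation
    phases, a workload/time model, and a seedable synthetic LIS data
    generator with fault injection for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
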