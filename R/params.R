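#' Built-in warning-rule categories
#'
#' Six rule categories are built in: `limit_range`, `delta_check`,
#' `combined_mode`, `sampling_time_validity`, `sample_abnormality` and
#' `qc_check`. The registry is extensible via [register_rule_category()] for
#' laboratories whose middleware defines further checks.
#'
#' @return Character vector of registered category names.
#' @export
#' @examples
#' rule_categories()
rule_categories <- function() names(.category_registry$validators)

.category_registry <- new.env(parent = emptyenv())
.category_registry$validators <- list()

#' Register an additional rule category
#'
#' Extension hook for rule categories beyond the six built-ins. The
#' validator receives the raw parameter list and must return the normalised
#' list or raise; the predicate receives `(params, test, history, panel)`
#' and must return `TRUE` (intercept) or `FALSE` (pass).
#'
#' @param name Category name (snake_case string).
#' @param validator Function normalising/validating a parameter list.
#' @param predicate Interception predicate function.
#' @return The category name, invisibly.
#' @export
register_rule_category <- function(name, validator, predicate) {
  stopifnot(is_scalar_chr(name), is.function(validator), is.function(predicate))
  .category_registry$validators[[name]] <- validator
  .category_registry$predicates[[name]] <- predicate
  invisible(name)
}

category_validator <- function(category) {
  v <- .category_registry$validators[[category]]
  if (is.null(v)) {
    abort(paste0("unknown rule category: '", category, "'"),
          class = "av_unknown_category")
  }
  v
}

category_predicate <- function(category) {
  .category_registry$predicates[[category]]
}

#' Validate and normalise rule parameters
#'
#' Checks a parameter record against its category's schema and returns the
#' normalised record. Normalisation fills defaults (inclusivity flags,
#' lookback windows, unlisted-pattern policy) and rejects unknown fields,
#' so a stored rule is always complete and unambiguous. Category names are
#' matched case-sensitively: a mis-cased category (`"Limit_Range"`) is an
#' error, because silent case mismatches in rule text are a documented
#' source of rules that never fire.
#'
#' @param category Rule category name, one of [rule_categories()].
#' @param params Named list of category-specific parameters.
#' @return The normalised parameter list.
#' @export
#' @examples
#' validate_rule_params("limit_range", list(intercept_at_or_above = 5, units = "mg/l"))
#' validate_rule_params("qc_check", list())
validate_rule_params <- function(category, params = list()) {
  if (!is_scalar_chr(category)) abort("category must be a string", class = "av_bad_input")
  if (is.null(params)) params <- list()
  if (!is.list(params)) abort("params must be a list", class = "av_bad_input")
  category_validator(category)(params)
}

check_no_extra <- function(params, allowed, category) {
  extra <- setdiff(names(params), allowed)
  if (length(extra)) {
    abort(paste0("unknown parameter(s) for ", category, ": ",
                 paste(extra, collapse = ", ")),
          class = "av_bad_params")
  }
}

check_threshold <- function(x, name) {
  if (!is_finite_num(x)) {
    abort(paste0(name, " must be a finite number"), class = "av_bad_params")
  }
  if (x < 0) abort(paste0(name, " must be >= 0"), class = "av_bad_params")
  as.numeric(x)
}

validate_limit_range <- function(params) {
  # sugar: intercept_at_or_above / intercept_at_or_below expand to a bound
  # with an explicit inclusivity flag
  if (!is.null(params$intercept_at_or_above)) {
    params$intercept_above <- params$intercept_at_or_above
    params$above_inclusive <- TRUE
    params$intercept_at_or_above <- NULL
  }
  if (!is.null(params$intercept_at_or_below)) {
    params$intercept_below <- params$intercept_at_or_below
    params$below_inclusive <- TRUE
    params$intercept_at_or_below <- NULL
  }
  check_no_extra(params, c("intercept_above", "intercept_below",
                           "above_inclusive", "below_inclusive", "units"),
                 "limit_range")
  if (is.null(params$intercept_above) && is.null(params$intercept_below)) {
    abort("limit_range needs intercept_above and/or intercept_below",
          class = "av_bad_params")
  }
  for (f in c("intercept_above", "intercept_below")) {
    if (!is.null(params[[f]])) {
      if (!is_finite_num(params[[f]])) {
        abort(paste0(f, " must be a finite number"), class = "av_bad_params")
      }
      params[[f]] <- as.numeric(params[[f]])
    }
  }
  params$above_inclusive <- isTRUE(params$above_inclusive %||% TRUE)
  params$below_inclusive <- isTRUE(params$below_inclusive %||% TRUE)
  params$units <- params$units %||% NA_character_
  params
}

validate_delta_check <- function(params) {
  check_no_extra(params, c("mode", "threshold", "lookback_days",
                           "trigger_when_no_history", "zero_fallback"),
                 "delta_check")
  params$mode <- params$mode %||% "percent"
  if (!params$mode %in% c("percent", "absolute")) {
    abort("delta mode must be 'percent' or 'absolute'", class = "av_bad_params")
  }
  params$threshold <- check_threshold(params$threshold, "delta threshold")
  params$lookback_days <- params$lookback_days %||% 7
  if (!is_finite_num(params$lookback_days) || params$lookback_days <= 0) {
    abort("lookback_days must be > 0", class = "av_bad_params")
  }
  params$lookback_days <- as.numeric(params$lookback_days)
  params$trigger_when_no_history <- isTRUE(params$trigger_when_no_history %||% FALSE)
  # percent mode with a prior of exactly zero cannot form a ratio; fall back
  # to an absolute comparison against zero_fallback (default: the percent
  # threshold reinterpreted in result units)
  params$zero_fallback <- check_threshold(params$zero_fallback %||% params$threshold,
                                          "zero_fallback")
  params
}

validate_combined_mode <- function(params) {
  check_no_extra(params, c("panel_analytes", "patterns", "unlisted_policy"),
                 "combined_mode")
  if (is.null(params$panel_analytes) || !is.character(params$panel_analytes) ||
      length(params$panel_analytes) < 2) {
    abort("combined_mode needs >= 2 panel_analytes", class = "av_bad_params")
  }
  pat <- params$patterns
  if (is.null(pat)) abort("combined_mode needs a patterns table", class = "av_bad_params")
  pat <- as.data.frame(pat, stringsAsFactors = FALSE)
  need <- c(params$panel_analytes, "flag")
  missing_cols <- setdiff(need, names(pat))
  if (length(missing_cols)) {
    abort(paste0("patterns table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "av_bad_params")
  }
  if (!all(pat$flag %in% c("contradictory", "allowed"))) {
    abort("pattern flag must be 'contradictory' or 'allowed'",
          class = "av_bad_params")
  }
  params$patterns <- pat[, need, drop = FALSE]
  params$unlisted_policy <- params$unlisted_policy %||% "intercept"
  if (!params$unlisted_policy %in% c("pass", "intercept")) {
    abort("unlisted_policy must be 'pass' or 'intercept'", class = "av_bad_params")
  }
  params
}

validate_sampling_time <- function(params) {
  check_no_extra(params, c("window_start", "window_end"), "sampling_time_validity")
  for (f in c("window_start", "window_end")) {
    v <- params[[f]]
    if (!is_scalar_chr(v) || !grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", v)) {
      abort(paste0(f, " must be a clock time 'HH:MM'"), class = "av_bad_params")
    }
  }
  params
}

validate_sample_abnormality <- function(params) {
  check_no_extra(params, "intercept_on", "sample_abnormality")
  flags <- params$intercept_on
  if (is.null(flags) || !is.character(flags) || length(flags) == 0) {
    abort("sample_abnormality needs intercept_on flags", class = "av_bad_params")
  }
  bad <- setdiff(flags, c("hemolysis", "lipemia"))
  if (length(bad)) {
    abort(paste0("unknown sample flag(s): ", paste(bad, collapse = ", ")),
          class = "av_bad_params")
  }
  params$intercept_on <- flags
  params
}

validate_qc_check <- function(params) {
  check_no_extra(params, character(), "qc_check")
  params
}
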