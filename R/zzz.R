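.onLoad <- function(libname, pkgname) {
  .category_registry$validators <- list()
  .category_registry$predicates <- list()
  register_rule_category("limit_range", validate_limit_range,
                         predicate_limit_range)
  register_rule_category("delta_check", validate_delta_check,
                         predicate_delta_check)
  register_rule_category("combined_mode", validate_combined_mode,
                         predicate_combined_mode)
  register_rule_category("sampling_time_validity", validate_sampling_time,
                         predicate_sampling_time)
  register_rule_category("sample_abnormality", validate_sample_abnormality,
                         predicate_sample_abnormality)
  register_rule_category("qc_check", validate_qc_check, predicate_qc_check)
  invisible()
}
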