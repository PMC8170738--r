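{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "autoverifyr rule definitions",
  "description": "A rule file is a JSON array of warning-rule objects. Category names and categorical match text are case-sensitive.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["rule_id", "analyte_code", "category"],
    "additionalProperties": false,
    "properties": {
      "rule_id": { "type": "string", "pattern": "^[0-9]{6}$" },
      "analyte_code": { "type": "string", "minLength": 1 },
      "category": {
        "enum": ["limit_range", "delta_check", "combined_mode",
                 "sampling_time_validity", "sample_abnormality", "qc_check"]
      },
      "params": { "type": "object" },
      "scope": {
        "type": "object",
        "additionalProperties": false,
        "properties": {
          "detection_systems": { "type": "array", "items": { "type": "string" } },
          "specimen_types": { "type": "array", "items": { "type": "string" } }
        }
      },
      "status": {
        "enum": ["pending_verification", "verified", "deleted"]
      }
    }
  }
}
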