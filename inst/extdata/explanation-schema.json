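{
  "title": "explanation document",
  "required": {
    "decision": "string",
    "rule": "array of rule terms",
    "contrast": "array of contrast items",
    "confidence": "object",
    "provenance": "object"
  },
  "rule_term_fields": ["feature", "feature_name", "op", "threshold"],
  "contrast_fields": ["feature_name", "reversed_op", "threshold", "delta_pct"],
  "confidence_fields": ["coverage_pct", "precision_pct", "prior_pct"]
}
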