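{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "gripscore/analysis-report/1.0",
  "title": "gripscore analysis report",
  "type": "object",
  "required": ["schema_version", "n_control", "n_patient", "scores",
               "improvement", "settings"],
  "properties": {
    "schema_version": {"type": "string"},
    "n_control": {"type": "integer", "minimum": 0},
    "n_patient": {"type": "integer", "minimum": 0},
    "functional_ids": {"type": "array", "items": {"type": "string"}},
    "nonfunctional_ids": {"type": "array", "items": {"type": "string"}},
    "scores": {
      "type": "object",
      "description": "group MAE summaries in %MVC",
      "additionalProperties": {
        "type": ["object", "null"],
        "required": ["mean", "sd", "n"],
        "properties": {
          "mean": {"type": "number"},
          "sd": {"type": ["number", "null"]},
          "n": {"type": "integer"}
        }
      }
    },
    "improvement": {"type": "object"},
    "baseline_contrast": {"type": ["object", "null"]},
    "correlation": {"type": ["object", "null"]},
    "agreement": {
      "type": ["object", "null"],
      "properties": {
        "bias": {"type": "number"},
        "bias_ci": {"type": "array", "minItems": 2, "maxItems": 2},
        "loa_lower": {"type": "number"},
        "loa_upper": {"type": "number"},
        "sd_diff": {"type": "number"},
        "n": {"type": "integer"}
      }
    },
    "improvement_correlation": {"type": ["object", "null"]},
    "settings": {"type": "object"}
  }
}
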