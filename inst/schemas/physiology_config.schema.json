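{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "brvpbpk physiology config",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "body_weight_kg": {"type": "number", "minimum": 40, "maximum": 150},
    "sex": {"enum": ["male", "female"]},
    "age_yr": {"type": "number", "minimum": 18, "maximum": 80},
    "disease": {
      "type": "object",
      "additionalProperties": false,
      "required": ["kind", "severity"],
      "properties": {
        "kind": {"enum": ["cirrhosis", "ckd"]},
        "severity": {"enum": ["CP_A", "CP_B", "CP_C", "moderate", "severe"]},
        "overrides": {"type": "object"}
      }
    }
  }
}
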