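{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "brvpbpk dosing regimen config",
  "type": "object",
  "additionalProperties": false,
  "required": ["route", "dose_mg"],
  "properties": {
    "route": {"enum": ["iv_bolus", "oral"]},
    "dose_mg": {"type": "number", "minimum": 0},
    "n_doses": {"type": "integer", "minimum": 1},
    "interval_h": {"type": "number", "exclusiveMinimum": 0},
    "infusion_duration_h": {"type": "number", "minimum": 0}
  }
}
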