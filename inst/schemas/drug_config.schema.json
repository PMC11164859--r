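{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "brvpbpk drug config",
  "type": "object",
  "additionalProperties": false,
  "required": ["molecular_weight_g_mol", "pka", "solubility_mg_ml", "log_p",
               "binding_protein", "intestinal_permeability_cm_min", "fu",
               "km_cyp2c19_uM", "kcat_cyp2c19_per_min",
               "renal_clearance_ml_min_kg"],
  "properties": {
    "name": {"type": "string"},
    "molecular_weight_g_mol": {"type": "number", "exclusiveMinimum": 0},
    "pka": {"type": "number"},
    "solubility_mg_ml": {"type": "number", "exclusiveMinimum": 0},
    "log_p": {"type": "number"},
    "binding_protein": {"enum": ["albumin", "AGP"]},
    "intestinal_permeability_cm_min": {"type": "number", "exclusiveMinimum": 0},
    "fu": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "fu_literature_range": {"type": "array", "items": {"type": "number"}},
    "km_cyp2c19_uM": {"type": "number", "exclusiveMinimum": 0},
    "kcat_cyp2c19_per_min": {"type": "number", "exclusiveMinimum": 0},
    "renal_clearance_ml_min_kg": {"type": "number", "exclusiveMinimum": 0},
    "blood_plasma_ratio": {"type": "number", "exclusiveMinimum": 0},
    "kery": {"type": "number", "exclusiveMinimum": 0},
    "ka_ap": {"type": "number", "minimum": 0}
  }
}
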