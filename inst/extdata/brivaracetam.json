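{
  "name": "brivaracetam",
  "molecular_weight_g_mol": 212.29,
  "pka": 7.07,
  "solubility_mg_ml": 850,
  "log_p": 1.04,
  "binding_protein": "albumin",
  "intestinal_permeability_cm_min": 3.36e-06,
  "fu": 0.61,
  "fu_literature_range": [
    0.79,
    0.83
  ],
  "km_cyp2c19_uM": 71.2,
  "kcat_cyp2c19_per_min": 0.81,
  "renal_clearance_ml_min_kg": 0.06,
  "kery": 1,
  "ka_ap": 0
}
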