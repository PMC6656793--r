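{
  "name": "fentanyl-like 17-state whole-body PBPK topology",
  "provenance": "synthetic-placeholder",
  "note": "Topology: arterial/venous blood, lung, nine perfused tissues, one extra liver and spleen sub-compartment, two extra gut sub-compartments; spleen and gut drain portally via the liver; liver is the only eliminating state. Numeric values are a synthetic placeholder parameter set (plausible adult human physiology, lipophilic-opioid-like partition coefficients), NOT a transcription of any published drug-specific parameter table.",
  "units": {"time": "min", "volume": "L", "amount": "ug", "flow": "L/min"},
  "output_state": "arterial",
  "dose": {"state": "arterial", "amount": 750},
  "physiology": [
    {"name": "arterial", "type": "arterial", "V": 1.5},
    {"name": "venous",   "type": "venous",   "V": 4.0},
    {"name": "lung",     "type": "lung",     "Q": 6.5,  "V": 0.5,  "Kp": 2.5},
    {"name": "liver",    "type": "tissue", "Q": 0.45, "V": 1.8,  "Kp": 4.0,  "CL": 0.9},
    {"name": "L_cpt_1",  "type": "sub",      "V": 0.4,  "parent": "liver",  "k_in": 0.05, "k_out": 0.12},
    {"name": "spleen",   "type": "tissue",   "Q": 0.2,  "V": 0.19, "Kp": 2.0,  "drains_to": "liver"},
    {"name": "S_cpt_1",  "type": "sub",      "V": 0.05, "parent": "spleen", "k_in": 0.04, "k_out": 0.10},
    {"name": "gut",      "type": "tissue",   "Q": 1.1,  "V": 1.1,  "Kp": 4.0,  "drains_to": "liver"},
    {"name": "G_cpt_1",  "type": "sub",      "V": 0.3,  "parent": "gut",    "k_in": 0.06, "k_out": 0.15},
    {"name": "G_cpt_2",  "type": "sub",      "V": 0.3,  "parent": "gut",    "k_in": 0.02, "k_out": 0.05},
    {"name": "brain",    "type": "tissue",   "Q": 0.75, "V": 1.45, "Kp": 4.0},
    {"name": "heart",    "type": "tissue",   "Q": 0.24, "V": 0.33, "Kp": 3.0},
    {"name": "kidney",   "type": "tissue",   "Q": 1.24, "V": 0.31, "Kp": 4.0},
    {"name": "muscle",   "type": "tissue",   "Q": 0.85, "V": 29.0, "Kp": 2.5},
    {"name": "skin",     "type": "tissue",   "Q": 0.30, "V": 3.3,  "Kp": 3.0},
    {"name": "adipose",  "type": "tissue",   "Q": 0.26, "V": 13.0, "Kp": 35.0},
    {"name": "rest",     "type": "tissue",   "Q": 1.11, "V": 4.0,  "Kp": 3.0}
  ]
}
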