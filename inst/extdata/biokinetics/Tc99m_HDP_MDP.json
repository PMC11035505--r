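{
  "name": "Tc99m-HDP/MDP bone scan",
  "nuclide": "Tc99m",
  "note": "Illustrative default transfer coefficients for a diphosphonate bone agent: roughly half of the administered activity is retained on bone mineral and half excreted in urine, with a fast-exchanging extracellular pool feeding both routes. Rates are user-editable configuration, not code; replace them with the compilation values of your choice for reference calculations.",
  "time_unit": "min",
  "injection_compartment": "blood",
  "excretion_sink": "kidneys",
  "compartments": {
    "blood": "Remainder",
    "soft_tissue": "Remainder",
    "bone": "Bone",
    "kidneys": "Kidneys"
  },
  "transfers": [
    { "from": "blood", "to": "bone", "rate_per_min": 0.010 },
    { "from": "blood", "to": "kidneys", "rate_per_min": 0.010 },
    { "from": "blood", "to": "soft_tissue", "rate_per_min": 0.025 },
    { "from": "soft_tissue", "to": "blood", "rate_per_min": 0.012 },
    { "from": "kidneys", "to": "bladder", "rate_per_min": 0.0347 }
  ]
}
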