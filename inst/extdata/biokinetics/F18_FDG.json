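{
  "name": "F18-FDG",
  "nuclide": "F18",
  "note": "Illustrative default transfer coefficients for fluorodeoxyglucose: rapid distribution from blood with metabolic trapping in brain, myocardium and other glucose-avid organs, hepatic exchange, and renal excretion to the bladder. Rates are user-editable configuration.",
  "time_unit": "min",
  "injection_compartment": "blood",
  "excretion_sink": "kidneys",
  "compartments": {
    "blood": "Blood",
    "brain": "Brain",
    "heart": "Heart",
    "lungs": "Lungs",
    "liver": "Liver",
    "pancreas": "Pancreas",
    "spleen": "Spleen",
    "kidneys": "Kidneys",
    "other": "Remainder"
  },
  "transfers": [
    { "from": "blood", "to": "brain", "rate_per_min": 0.009 },
    { "from": "blood", "to": "heart", "rate_per_min": 0.0035 },
    { "from": "blood", "to": "lungs", "rate_per_min": 0.002 },
    { "from": "blood", "to": "liver", "rate_per_min": 0.0045 },
    { "from": "blood", "to": "pancreas", "rate_per_min": 0.0007 },
    { "from": "blood", "to": "spleen", "rate_per_min": 0.0007 },
    { "from": "blood", "to": "kidneys", "rate_per_min": 0.004 },
    { "from": "blood", "to": "other", "rate_per_min": 0.045 },
    { "from": "other", "to": "blood", "rate_per_min": 0.015 },
    { "from": "liver", "to": "blood", "rate_per_min": 0.005 },
    { "from": "kidneys", "to": "bladder", "rate_per_min": 0.06 }
  ]
}
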