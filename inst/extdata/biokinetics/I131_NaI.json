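{
  "name": "Na131I iodide",
  "nuclide": "I131",
  "note": "Illustrative default transfer coefficients for systemic iodide: competition between thyroid uptake (about a quarter of administered activity) and renal excretion, with secretion into salivary glands and gastric contents, intestinal transit and near-complete reabsorption, and long thyroid retention. Rates are user-editable configuration.",
  "time_unit": "min",
  "injection_compartment": "blood",
  "excretion_sink": "kidneys",
  "compartments": {
    "blood": "Blood",
    "thyroid": "Thyroid",
    "kidneys": "Kidneys",
    "salivary": "Salivary glands",
    "stomach_wall": "Stomach wall",
    "si_content": "Small intestine content",
    "rc_content": "Right colon content",
    "lc_content": "Left colon content",
    "rs_content": "Recto-sigmoid colon content",
    "liver": "Liver",
    "other": "Remainder"
  },
  "transfers": [
    { "from": "blood", "to": "thyroid", "rate_per_min": 0.0011 },
    { "from": "blood", "to": "kidneys", "rate_per_min": 0.0025 },
    { "from": "blood", "to": "salivary", "rate_per_min": 0.0005 },
    { "from": "blood", "to": "stomach_wall", "rate_per_min": 0.0008 },
    { "from": "blood", "to": "liver", "rate_per_min": 0.0010 },
    { "from": "blood", "to": "other", "rate_per_min": 0.030 },
    { "from": "other", "to": "blood", "rate_per_min": 0.030 },
    { "from": "liver", "to": "blood", "rate_per_min": 0.010 },
    { "from": "salivary", "to": "stomach_wall", "rate_per_min": 0.020 },
    { "from": "stomach_wall", "to": "si_content", "rate_per_min": 0.015 },
    { "from": "si_content", "to": "blood", "rate_per_min": 0.015 },
    { "from": "si_content", "to": "rc_content", "rate_per_min": 0.002 },
    { "from": "rc_content", "to": "lc_content", "rate_per_min": 0.0008 },
    { "from": "lc_content", "to": "rs_content", "rate_per_min": 0.0008 },
    { "from": "thyroid", "to": "blood", "rate_per_min": 0.000006 },
    { "from": "kidneys", "to": "bladder", "rate_per_min": 0.02 }
  ]
}
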