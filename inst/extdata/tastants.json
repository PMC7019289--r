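[
  {
    "name": "citric_acid",
    "taste": "sour",
    "c_min_mM": 0.015,
    "c_max_mM": 46.846,
    "n_levels": 14,
    "start_mM": 7.328
  },
  {
    "name": "nacl",
    "taste": "salty",
    "c_min_mM": 0.342,
    "c_max_mM": 342.231,
    "n_levels": 12,
    "start_mM": 97.469
  },
  {
    "name": "quinine_hcl",
    "taste": "bitter",
    "c_min_mM": 7.7e-05,
    "c_max_mM": 3.131,
    "n_levels": 21,
    "start_mM": 0.077
  },
  {
    "name": "sucrose",
    "taste": "sweet",
    "c_min_mM": 0.073,
    "c_max_mM": 584.283,
    "n_levels": 14,
    "start_mM": 73.509
  }
]
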