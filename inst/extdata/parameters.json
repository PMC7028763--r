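{
  "schema_version": 1,
  "currency": "USD 2017",
  "parameters": {
    "n_census":     {"baseline": 355,    "low": 100,    "high": 600,     "kind": "count"},
    "p_is_msu":     {"baseline": 0.53,   "low": 0.43,   "high": 0.63,    "kind": "probability"},
    "p_is_st":      {"baseline": 0.53,   "low": 0.43,   "high": 0.63,    "kind": "probability"},
    "p_mimic":      {"baseline": 0.27,   "low": 0.02,   "high": 0.31,    "kind": "probability"},
    "p_elig_msu":   {"baseline": 0.82,   "low": 0.72,   "high": 0.92,    "kind": "probability"},
    "p_elig_st":    {"baseline": 0.75,   "low": 0.65,   "high": 0.85,    "kind": "probability"},
    "p_recv_msu":   {"baseline": 0.95,   "low": 0.89,   "high": 0.98,    "kind": "probability"},
    "p_recv_st":    {"baseline": 0.95,   "low": 0.90,   "high": 0.99,    "kind": "probability"},
    "p_csc":        {"baseline": 0.42,   "low": 0.36,   "high": 0.56,    "kind": "probability"},
    "p_tx_is":      {"baseline": 0.41,   "low": 0.13,   "high": 0.68,    "kind": "probability"},
    "p_tx_hem":     {"baseline": 0.80,   "low": 0.60,   "high": 0.90,    "kind": "probability"},
    "p_tx_mimic":   {"baseline": 0.10,   "low": 0.01,   "high": 0.19,    "kind": "probability"},
    "p_air_is":     {"baseline": 0.50,   "low": 0.40,   "high": 0.60,    "kind": "probability"},
    "p_air_hem":    {"baseline": 0.98,   "low": 0.95,   "high": 0.99,    "kind": "probability"},
    "p_air_ok":     {"baseline": 0.95,   "low": 0.80,   "high": 0.99,    "kind": "probability"},
    "c_ct":         {"baseline": 253,    "low": 190,    "high": 316,     "kind": "cost"},
    "c_tpa":        {"baseline": 188,    "low": 141,    "high": 235,     "kind": "cost"},
    "c_obs":        {"baseline": 71,     "low": 53,     "high": 89,      "kind": "cost"},
    "c_ed_is":      {"baseline": 749,    "low": 563,    "high": 964,     "kind": "cost"},
    "c_ed_hem":     {"baseline": 749,    "low": 563,    "high": 964,     "kind": "cost"},
    "c_tele":       {"baseline": 28,     "low": 21,     "high": 35,      "kind": "cost"},
    "c_air":        {"baseline": 7412,   "low": 5559,   "high": 9265,    "kind": "cost"},
    "c_ground":     {"baseline": 723,    "low": 542,    "high": 904,     "kind": "cost"},
    "c_msu_annual": {"baseline": 600000, "low": 500000, "high": 1200000, "kind": "cost"}
  }
}
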