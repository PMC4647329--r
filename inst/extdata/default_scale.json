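{
  "cutoff": 9.5,
  "items": [
    {
      "name": "age_degree",
      "weight": 1,
      "kind": "threshold",
      "variable": "age",
      "points": [0, 1],
      "thresholds": 56.44
    },
    {
      "name": "history_dm",
      "weight": 1,
      "kind": "binary",
      "variable": "hx_dm",
      "points": [0, 1]
    },
    {
      "name": "anxiety_day1",
      "weight": 1,
      "kind": "binary",
      "variable": "sym_anxiety_d1",
      "points": [0, 1]
    },
    {
      "name": "nihss_day1_degree",
      "weight": 1,
      "kind": "threshold",
      "variable": "nihss_d1",
      "points": [0, 1, 2],
      "thresholds": [2, 6]
    },
    {
      "name": "irritability_day1",
      "weight": 1.5,
      "kind": "binary",
      "variable": "sym_irritability_d1",
      "points": [0, 1.5]
    },
    {
      "name": "delta_nihss_degree",
      "weight": 1,
      "kind": "threshold",
      "variable": "delta_nihss",
      "points": [0, 1],
      "thresholds": -1
    },
    {
      "name": "circumrotating_change",
      "weight": 2,
      "kind": "change",
      "variable": "circumrotating",
      "points": [0, 2, 4]
    },
    {
      "name": "tinnitus_change",
      "weight": 2.5,
      "kind": "change",
      "variable": "tinnitus",
      "points": [0, 2.5, 5]
    }
  ]
}
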