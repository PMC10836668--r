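{
  "mode": "start",
  "criterion": "2.5",
  "response": "start_doy_2_5",
  "window": {
    "start_md": "01-28",
    "end_md": "03-07"
  },
  "variables": ["T", "H", "Rf", "Sd", "Wd", "Wg"],
  "a": 137.151,
  "b": {
    "T": -3.931,
    "H": -0.570,
    "Rf": 0.010,
    "Sd": -0.053,
    "Wd": 0.170,
    "Wg": 2.282
  },
  "loocv_mae": 1.0,
  ".class": "pollen_lm"
}
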