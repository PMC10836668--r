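{
  "mode": "start",
  "criterion": "5",
  "response": "start_doy_5",
  "window": {
    "start_md": "01-28",
    "end_md": "03-10"
  },
  "variables": ["T", "H", "Rf", "Cc", "Sd", "Wd", "Wg"],
  "a": 177.358,
  "b": {
    "T": -4.409,
    "H": -0.491,
    "Rf": 0.011,
    "Cc": -0.391,
    "Sd": -0.098,
    "Wd": 0.154,
    "Wg": 2.186
  },
  "loocv_mae": 1.4,
  ".class": "pollen_lm"
}
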