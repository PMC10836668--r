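{
  "mode": "peak",
  "criterion": "5",
  "response": "peak_doy",
  "window": {
    "start_md": "02-20",
    "end_md": "mps-start"
  },
  "variables": ["start_day", "T", "H", "Cc", "Sd", "Ws", "Wd", "Wg"],
  "a": 90.623,
  "b": {
    "start_day": -0.301,
    "T": -1.183,
    "H": 0.016,
    "Cc": -0.187,
    "Sd": -0.031,
    "Ws": -1.039,
    "Wd": 0.371,
    "Wg": -0.126
  },
  "loocv_mae": 0.4,
  ".class": "pollen_lm"
}
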