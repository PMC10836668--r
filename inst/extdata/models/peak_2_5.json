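{
  "mode": "peak",
  "criterion": "2.5",
  "response": "peak_doy",
  "window": {
    "start_md": "02-07",
    "end_md": "mps-start"
  },
  "variables": ["start_day", "T", "Rf", "Cc", "Sd", "Wd", "Wg"],
  "a": 97.853,
  "b": {
    "start_day": 0.635,
    "T": -1.249,
    "Rf": -0.026,
    "Cc": -0.534,
    "Sd": -0.111,
    "Wd": 0.138,
    "Wg": 1.105
  },
  "loocv_mae": 0.7,
  ".class": "pollen_lm"
}
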