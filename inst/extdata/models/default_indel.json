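{
  "variables": ["nvs", "mean_nbq", "mean_variation_rate", "read_end_ratio"],
  "intercept": -13.5660573677431,
  "coefficients": [0.107712371130613, 0.571909980666902, -203.752585949265, 2.63163002135846],
  "platform": "synthetic",
  "provenance": "trained on exovar-simulated reads (seed 224737), labels from planted truth, resampled to 10% TP"
}
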