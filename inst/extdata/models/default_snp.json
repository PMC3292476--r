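{
  "variables": ["ref_var_ratio", "mean_var_base_quality", "mean_nbq", "mean_dist3", "strand_both", "nbq_x_dist3", "strand_x_dist3"],
  "intercept": -7.58666983436392,
  "coefficients": [-0.765810265138019, 0.706758645257517, -0.440585429903065, 0.474106085129099, 2.62891030741238, -0.0122432817158277, -0.0969637208008943],
  "platform": "synthetic",
  "provenance": "trained on exovar-simulated reads (seed 104729), labels from planted truth, resampled to 10% TP"
}
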