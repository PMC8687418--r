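{
  "model": "immigration_death",
  "theta_true": [0.6, 0.03],
  "x0": "steady_state",
  "n_points": 21,
  "dt": 2,
  "n_replicates": 5,
  "base_seed": 1
}
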