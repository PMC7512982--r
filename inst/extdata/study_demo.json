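{
  "contaminants": {
    "N(5,1)": {"family": "normal", "theta": [5, 1]},
    "N(0,9)": {"family": "normal", "theta": [0, 3]}
  },
  "epsilon_grid": [0.1, 0.3, 0.5],
  "n_grid": [200],
  "reps": 10,
  "measures": ["tv", "kld", "pistar"],
  "seed": 1
}
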