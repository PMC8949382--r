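{
  "synthetic": { "preset": "paper_like", "n_participants": 60 },
  "rules": {},
  "pruning": { "policy": "paper_list", "threshold": 0.9 },
  "G_list": [1, 2, 3],
  "n_starts": 2,
  "max_iter": 200,
  "predictor_criterion": "AIC",
  "seed": 20260911
}
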