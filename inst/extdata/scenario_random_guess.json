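{
  "probs": [[0.5, 0.5, 0.0], [0.5, 0.5, 0.0]],
  "n": [100, 100],
  "seed": 1,
  "arms": ["A", "B"]
}
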