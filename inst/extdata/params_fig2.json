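{
  "model": "base",
  "a": 0.514,
  "b": 1.02e-9,
  "k": 1e-4,
  "sigma": 10,
  "d": 2e-2,
  "m": -1e-6
}
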