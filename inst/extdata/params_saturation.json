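{
  "model": "saturation",
  "a": 0.514,
  "b": 1.02e-9,
  "k": 1e-3,
  "sigma": 10,
  "d": 1e-2,
  "b_e": 0.1,
  "kappa_e": 1e5,
  "d_e": 2,
  "kappa_d": 1e4
}
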