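{
  "model": "nkctl",
  "a": 0.514,
  "b": 1.02e-9,
  "c": 1.5e-3,
  "k": 1e-3,
  "sigma": 10,
  "mu": 2e-2,
  "b_n": 0.1,
  "kappa_bn": 1e5,
  "d_n": 1,
  "kappa_dn": 1e4,
  "d": 1e-2,
  "b_e": 0.1,
  "kappa_be": 1e5,
  "d_e": 2,
  "kappa_de": 1e4,
  "omega": 1e-10
}
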