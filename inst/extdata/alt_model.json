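{
  "model": "alt_model_params",
  "k1": 0.28,
  "kmax": 2.54,
  "km1": 0.133,
  "k2": 0.001368,
  "km2": 0.028,
  "k3": 1,
  "DT": 0.011,
  "DD": 1.21,
  "DI": 10,
  "Cdc42_tot": 1
}
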