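{
  "model": "negative_feedback_params",
  "k1a": 10,
  "k1b": 10,
  "k2a": 0.16,
  "k2b": 0.35,
  "k3": 0.35,
  "k4a": 10,
  "k4b": 10,
  "k5a": 36,
  "k5b": 0.65,
  "k7": 10,
  "Dm": 0.036,
  "Cdc42_tot": 5,
  "BemGEF_tot": 0.017,
  "k8max": 0.0063,
  "k8h": 6,
  "k8n": 10,
  "k9max": 0.0044,
  "k9h": 6,
  "k9n": 10.003
}
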