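{
  "model": "septin_params",
  "k1a": 10,
  "k1b": 10,
  "k2a": 0.16,
  "k2b": 0.63,
  "k3": 0.35,
  "k4a": 10,
  "k4b": 10,
  "k5a": 144,
  "k5b": 20.8,
  "k7": 10,
  "k12a": 10,
  "k12b": 10,
  "k13": 1.5,
  "k15": 1,
  "k16": 0.05,
  "k17": 0.125,
  "k18": 0.1,
  "k19": 4.5,
  "k20": 0.2,
  "k21": 0.65,
  "k22": 10.5,
  "k23": 26,
  "k24": 0.1,
  "k25": 5.5,
  "Dm": 0.036,
  "Dp": 0.00025,
  "Cdc42_tot": 5,
  "BemGEF_tot": 0.017,
  "GapS_tot": 0.2,
  "Axl2_tot": 0.2,
  "Septin_tot": 5
}
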