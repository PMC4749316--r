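{
  "R1_insp": 3,
  "R2_exp": 3,
  "R2_insp": 300,
  "R1_exp": 3,
  "gamma": 1,
  "C_tot": 450
}
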