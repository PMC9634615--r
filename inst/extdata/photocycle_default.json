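{
  "tau_C": 39,
  "tau_A": 15,
  "tau_B": 67,
  "ps_L_fraction": 0.65,
  "dark_A_fraction": 0.5,
  "delays": [2, 3, 7, 10, 13, 21, 35, 51, 62, 62, 67, 72, 80, 90, 130, 166, 258, 630, 1620],
  "noise_sigma_occ": 0.03,
  "seed": 1
}
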