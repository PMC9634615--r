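{
  "tau": 40,
  "rate": 2,
  "duration": 300,
  "dark_band_centres": [446, 475],
  "light_band_centre": 390,
  "dark_band_widths": [15, 15],
  "light_band_width": 30,
  "dark_band_amplitudes": [0.50, 0.45],
  "light_band_amplitude": 0.40,
  "ps_L_fraction": 0.65,
  "baseline_offset": 0.05
}
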