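name: na_ssi
holding: -120.0
reversal: 50.0
feature: normalized_peak
normalization: max_over_sweep
sweep:
- -120.0
- -110.0
- -100.0
- -90.0
- -80.0
- -70.0
- -60.0
- -50.0
- -40.0
- -30.0
- -20.0
- -10.0
- 0.0
- 10.0
- 20.0
steps:
- voltage: sweep
  duration: 200.0
- voltage: -20.0
  duration: 20.0
  record: yes
  dt: 0.005
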