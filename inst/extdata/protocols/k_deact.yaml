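name: k_deact
holding: -80.0
reversal: -90.0
feature: min_abs_current_over_driving_force
normalization: max_over_sweep
sweep:
- -120.0
- -100.0
- -80.0
- -60.0
- -40.0
- -20.0
- 0.0
steps:
- voltage: 60.0
  duration: 2.0
- voltage: sweep
  duration: 4.0
  record: yes
  dt: 0.01
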