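name: k_act
holding: -100.0
reversal: -90.0
feature: peak_conductance_over_driving_force
normalization: max_over_sweep
sweep:
- -100.0
- -80.0
- -60.0
- -40.0
- -20.0
- 0.0
- 20.0
- 40.0
- 60.0
steps:
- voltage: sweep
  duration: 4.0
  record: yes
  dt: 0.01
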