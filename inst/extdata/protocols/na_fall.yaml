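name: na_fall
holding: -100.0
reversal: 50.0
feature: fall_time_90_20
normalization: none
sweep:
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
  duration: 20.0
  record: yes
  dt: 0.005
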