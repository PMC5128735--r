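name: na_rec
holding: -120.0
reversal: 50.0
feature: peak_ratio
normalization: none
sweep:
- 1.0
- 2.0
- 5.0
- 10.0
- 20.0
- 50.0
- 100.0
- 200.0
- 500.0
- 1000.0
steps:
- voltage: -20.0
  duration: 200.0
  record: yes
  dt: 0.005
- voltage: -120.0
  duration: sweep
- voltage: -20.0
  duration: 20.0
  record: yes
  dt: 0.005
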