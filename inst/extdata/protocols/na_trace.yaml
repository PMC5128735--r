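name: na_trace
holding: -100.0
reversal: 50.0
feature: normalized_trace
normalization: none
sweep:
- -10.0
steps:
- voltage: sweep
  duration: 5.0
  record: yes
  dt: 0.005
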