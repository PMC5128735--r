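name: k_trace_0
holding: -80.0
reversal: -90.0
feature: normalized_trace
normalization: none
sweep:
- 0.0
steps:
- voltage: sweep
  duration: 4.0
  record: yes
  dt: 0.01
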