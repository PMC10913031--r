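# Global alert-protection minimum with a marginal neutral well (T0 < T < T*).
parameters:
  h_ext: 0
  h_int: 1
  a0: 1
  b: 1
  T: 5.1
  T0: 5
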