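# Mixed state below the innate critical context with alarming history.
parameters:
  h_ext: 0
  h_int: 3
  a0: 1
  b: 1
  T: 4
  T0: 5
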