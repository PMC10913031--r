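# Balanced double-well ("baby") landscape: no historical or expert bias,
# sensory context below the innate critical context.
parameters:
  h_ext: 0
  h_int: 0
  a0: 1
  b: 1
  T: 4
  T0: 5
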