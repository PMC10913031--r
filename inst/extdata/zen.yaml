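# Single neutral minimum: context above the critical context, no biases.
parameters:
  h_ext: 0
  h_int: 0
  a0: 1
  b: 1
  T: 6
  T0: 5
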