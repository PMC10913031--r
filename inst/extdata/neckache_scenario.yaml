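# Synthetic illustrative scenario: the learning and unlearning of a
# persistent neckache as ordered parameter changes. The numbers are a
# toolkit choice satisfying the regime inequalities; the narrative sequence
# is: neutral context -> uncertainty with survival bias -> catastrophizing
# -> hypervigilance bias -> nocebo deepening -> neurobiological education
# -> belief revision -> communicative landscape.
parameters:
  h_ext: 0
  h_int: 0
  a0: 1
  b: 1
  T: 8
  T0: 5
scenario:
  steps:
    - label: persistent novel ache
      T: 7
      h_int: 3
    - label: focus narrows
      T: 6
    - label: sensory withdrawal
      T: 4
    - label: nocebo posture message
      h_ext: -0.5
    - label: NBE session 1
      h_ext: 0
    - label: NBE session 2
      h_ext: 0.5
    - label: belief revision
      h_int: -1
    - label: sensory training
      T: 6
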