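- type: C
  h: 0.0
  k: 1.0
- type: N1
  h: 0.51
  k: 1.02
- type: N2
  h: 1.37
  k: 0.89
- type: O1
  h: 0.97
  k: 1.06
- type: O2
  h: 2.09
  k: 0.66
- type: S1
  h: 0.46
  k: 0.81
- type: S2
  h: 1.11
  k: 0.69
- type: P1
  h: 0.19
  k: 0.77
- type: P2
  h: 0.75
  k: 0.76
- type: F
  h: 2.71
  k: 0.52
- type: Cl
  h: 1.48
  k: 0.62
- type: Br
  h: 1.5
  k: 0.54
- type: I
  h: 1.35
  k: 0.45
- type: B
  h: -0.45
  k: 0.73
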