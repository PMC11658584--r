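package: codepend
version: 1.0.0
seed: 20241219
parameters:
  xi: 0.8
  a1: 0.00479
  a2: 0.035
  delta1: 0.00767
  delta2: 0.217
  k1: 0.01923
  mu: 0.0952
  phi1: 9.0e-06
  phi2: 0.175
  phi3: 0.175009
  gamma1: 0.7
  gamma2: 0.00575
  gamma3: 0.352875
initial_state:
  S: 0.6
  D: 0.2
  M: 0.1
  Dm: 0.06
  Rd: 0.02
  Rm: 0.0
  Rdm: 0.0
horizon: 52.0
step: 0.01
weights:
  A1: 100.0
  A2: 100.0
  A3: 100.0
  w1: 0.5
  w2: 0.5
  w3: 0.5
  w4: 0.5
  w5: 0.5
enabled_controls:
- 1
- 2
- 3
- 4
- 5
lhs:
  n_samples: 2000.0
  seed: 2.0241219e+07
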