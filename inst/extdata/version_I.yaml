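# Stochastic-model parameter set, version I (initial parameter set).
# theta/H keys are REGULATOR.TARGET edges; gene order BCL6, IRF4, BLIMP1.
version: I
gamma: 2
genes:
  BCL6:
    s0: 100
    d0: 0.05
    s1: 100
    d1: 0.138
    konInit: 0.1
    koffInit: 1
    konMin: 0.001
    konMax: 2
    koffMin: 0.01
    koffMax: 10
  IRF4:
    s0: 1
    d0: 0.05
    s1: 160
    d1: 0.173
    konInit: 0.0017
    koffInit: 1
    konMin: 0.001
    konMax: 2
    koffMin: 0.01
    koffMax: 10
  BLIMP1:
    s0: 1
    d0: 0.1733
    s1: 40
    d1: 0.173
    konInit: 0.1
    koffInit: 1
    konMin: 0.001
    konMax: 2
    koffMin: 0.01
    koffMax: 10
theta:
  BCL6.BCL6: -0.2
  IRF4.BCL6: -100
  BLIMP1.BCL6: -20
  BCR.BCL6: -20
  IRF4.IRF4: 5
  CD40.IRF4: 40
  BCL6.BLIMP1: -1
  IRF4.BLIMP1: 40
H:
  BCL6.BCL6: 1
  IRF4.BCL6: 0.1
  BLIMP1.BCL6: 1
  BCR.BCL6: 0.01
  IRF4.IRF4: 0.01
  CD40.IRF4: 1
  BCL6.BLIMP1: 0.1
  IRF4.BLIMP1: 0.01
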