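# Stochastic-model parameter set, version III (after semi-manual tuning).
# BLIMP1 konMin is lowered to keep konInit strictly inside the admissible
# calibration interval (konMin < konInit).
version: III
gamma: 2
genes:
  BCL6:
    s0: 100
    d0: 0.05
    s1: 100
    d1: 0.138
    konInit: 0.15
    koffInit: 1
    konMin: 0.001
    konMax: 2
    koffMin: 0.01
    koffMax: 10
  IRF4:
    s0: 2.1
    d0: 0.05
    s1: 160
    d1: 0.173
    konInit: 0.007
    koffInit: 1
    konMin: 0.001
    konMax: 2
    koffMin: 0.01
    koffMax: 10
  BLIMP1:
    s0: 100
    d0: 0.007
    s1: 40
    d1: 0.173
    konInit: 0.001
    koffInit: 1
    konMin: 0.0001
    konMax: 2
    koffMin: 0.01
    koffMax: 10
theta:
  BCL6.BCL6: -0.2
  IRF4.BCL6: -50
  BLIMP1.BCL6: -0.5
  BCR.BCL6: -200
  IRF4.IRF4: 11
  CD40.IRF4: 10
  BCL6.BLIMP1: -1
  IRF4.BLIMP1: 50
H:
  BCL6.BCL6: 0.1
  IRF4.BCL6: 0.01
  BLIMP1.BCL6: 0.01
  BCR.BCL6: 0.001
  IRF4.IRF4: 0.1
  CD40.IRF4: 1
  BCL6.BLIMP1: 0.01
  IRF4.BLIMP1: 0.1
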