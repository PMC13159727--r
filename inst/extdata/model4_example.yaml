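model: model4_SE_NC_admix
fixed:
  N_SW: 5000.0
  N_SE: 1000.0
  N_C: 8000.0
  N_NC: 1000.0
  N_N: 3000.0
  N_ANC: 5000.0
  m: 1.0e-04
free:
  T_SWC: [100.0, 50000.0]
  T_CN: [100.0, 50000.0]
  T_NC: [100.0, 50000.0]
  T_SE: [100.0, 50000.0]
  a_SE: [0.0, 1.0]
  a_NC: [0.0, 1.0]
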