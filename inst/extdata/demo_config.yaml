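n_patients: 33
seed: 1
sim:
  sigma_patient: 0.5
  sigma_residual: 1.0
pool_bilateral: yes
adjust_bh: no
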