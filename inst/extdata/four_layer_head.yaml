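name: four-layer slab head model
wavelength: 785.0
layers:
- name: scalp
  mua: 0.019
  mus: 6.6
  g: 0.89
  thickness: 5.0
  DB: 1.0e-06
  alpha: 1.0
  n0: 1.37
- name: skull
  mua: 0.014
  mus: 8.6
  g: 0.89
  thickness: 7.0
  DB: 8.0e-08
  alpha: 1.0
  n0: 1.37
- name: CSF
  mua: 0.001
  mus: 0.002
  g: 0.89
  thickness: 2.0
  DB: 1.0e-08
  alpha: 1.0
  n0: 1.37
- name: brain
  mua: 0.02
  mus: 11.0
  g: 0.89
  thickness: Inf
  DB: 6.0e-06
  alpha: 1.0
  n0: 1.37
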