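# Per-soil-type biotic ligand model parameter presets used as simulation
# truth by generate_blm_dataset().  Affinity constants in 1/M, totals and
# ligand concentration in mM.  Values are representative of fitted
# parameter sets for the four soil types: sandy soils carry weak, abundant
# sites with little proton competition; andosols strong proton/Ca
# competition; cohesive soils a very high Cd affinity.
sandy:
  k_cd: 2400
  k_ca: 25
  k_mg: 24
  k_h: 39
  ca0: 2.2
  mg0: 1.0
  h0: 0.0004
  l0: 11.0
andosol:
  k_cd: 3650
  k_ca: 806
  k_mg: 387
  k_h: 241
  ca0: 0.59
  mg0: 0.33
  h0: 0.26
  l0: 2.6
brown_forest:
  k_cd: 1006
  k_ca: 716
  k_mg: 610
  k_h: 171
  ca0: 0.31
  mg0: 0.38
  h0: 0.13
  l0: 4.3
cohesive:
  k_cd: 16634
  k_ca: 877
  k_mg: 237
  k_h: 88
  ca0: 4.95
  mg0: 0.58
  h0: 0.0026
  l0: 9.1
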