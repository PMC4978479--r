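name: set1 (Brachypodium distachyon)
chr_pair: 5
l_arm_c:
  - [6, 7]
  - [5, 6]
  - [5, 6]
  - [2, 7]
  - [1, 5]
l_arm_d:
  - [37, 37]
  - [29, 29]
  - [29, 30]
  - [11, 36]
  - [6, 21]
min_rad_nu: 3500
max_rad_nu: 4000
min_vol_no: 0.02
max_vol_no: 0.05
rad_bead: 250
eps_1: 25
eps_2: 50
multi: 1
restart_after: 500000

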