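name: set3 (Miscanthus-like)
chr_pair: 19
l_arm_c:
  - [3, 4]
  - [3, 4]
  - [3, 3]
  - [3, 3]
  - [3, 3]
  - [2, 3]
  - [2, 3]
  - [2, 3]
  - [2, 3]
  - [2, 2]
  - [2, 2]
  - [2, 2]
  - [1, 2]
  - [1, 2]
  - [1, 2]
  - [1, 2]
  - [1, 1]
  - [1, 1]
  - [1, 1]
l_arm_d:
  - [121, 122]
  - [117, 117]
  - [113, 113]
  - [108, 109]
  - [104, 104]
  - [99, 100]
  - [95, 96]
  - [91, 91]
  - [86, 87]
  - [82, 83]
  - [78, 78]
  - [73, 74]
  - [69, 69]
  - [65, 65]
  - [60, 61]
  - [56, 56]
  - [51, 52]
  - [47, 48]
  - [43, 43]
min_rad_nu: 8200
max_rad_nu: 9200
min_vol_no: 0.02
max_vol_no: 0.05
rad_bead: 250
eps_1: 25
eps_2: 50
multi: 1
restart_after: 500000

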