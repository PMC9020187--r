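# Nonbonded pair coefficients for the seven bead types of the Bis-GMA/TEGDMA
# coarse-grain model. SYNTHETIC stand-in table in the style of the Martini 3
# interaction matrix: sigmas follow the regular/small/tiny size-pair
# convention; epsilons are plausible-scale values graded by chemical-class
# polarity. For production work substitute the published Martini 3 matrix
# (same file format). See the package vignette for details.

[masses]
regular 72
small 54
tiny 36

[pairs]
SC4   SC4   0.410 2.710
SC4   N4a   0.440 2.904
SC4   TP1   0.375 2.140
SC4   TN2a  0.375 2.274
SC4   TC5   0.375 2.341
SC4   SC2   0.410 2.246
SC4   SN3a  0.410 2.556
N4a   N4a   0.470 4.500
N4a   TP1   0.405 3.344
N4a   TN2a  0.405 2.964
N4a   TC5   0.405 2.508
N4a   SC2   0.440 2.376
N4a   SN3a  0.440 3.960
TP1   TP1   0.340 2.888
TP1   TN2a  0.340 2.195
TP1   TC5   0.340 1.848
TP1   SC2   0.375 1.739
TP1   SN3a  0.375 2.943
TN2a  TN2a  0.340 2.310
TN2a  TC5   0.340 1.964
TN2a  SC2   0.375 1.873
TN2a  SN3a  0.375 2.608
TC5   TC5   0.340 2.022
TC5   SC2   0.375 1.940
TC5   SN3a  0.375 2.207
SC2   SC2   0.410 2.323
SC2   SN3a  0.410 2.091
SN3a  SN3a  0.410 3.485
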