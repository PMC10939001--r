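71
Lattice="0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000" Properties=species:S:1:pos:R:3:tags:S:1:frozen:I:1 pbc="F F F"
O 1.41421356 0.00000000 0.25000000 adsorbate 0
C 0.70710678 1.22474487 -0.25000000 adsorbate 0
C -0.70710678 1.22474487 0.25000000 adsorbate 0
C -1.41421356 0.00000000 -0.25000000 adsorbate 0
C -0.70710678 -1.22474487 0.25000000 adsorbate 0
C 0.70710678 -1.22474487 -0.25000000 adsorbate 0
H 0.70696865 1.22450562 -1.34999997 adsorbate 0
O -1.38115537 2.39223127 -0.22700525 adsorbate 0
H -0.70696865 1.22450562 1.34999997 adsorbate 0
O -2.76231074 0.00000000 0.22700525 adsorbate 0
H -1.41393730 0.00000000 -1.34999997 adsorbate 0
O -1.38115537 -2.39223127 -0.22700525 adsorbate 0
H -0.70696865 -1.22450562 1.34999997 adsorbate 0
H 0.70696865 -1.22450562 -1.34999997 adsorbate 0
H 1.22560569 -2.12281133 0.11692712 adsorbate 0
H -2.29124949 2.37077159 0.10790993 adsorbate 0
H -3.19877317 -0.79889447 -0.10790993 adsorbate 0
H -0.90752368 -3.16966606 0.10790993 adsorbate 0
O 2.58591578 3.51184589 -3.09856348 adsorbate 0
C 1.64554772 4.66860990 -3.26471080 adsorbate 0
C 1.50307220 5.38900960 -1.95676394 adsorbate 0
C 0.95939119 4.44704764 -0.92374959 adsorbate 0
C 1.89975925 3.29028363 -0.75760227 adsorbate 0
C 2.04223477 2.56988393 -2.06554913 adsorbate 0
H 0.66170830 4.29768722 -3.58793883 adsorbate 0
O 0.60632691 6.49156493 -2.11525566 adsorbate 0
H 2.48698911 5.75952230 -1.63330166 adsorbate 0
O 0.82391728 5.13389608 0.32316101 adsorbate 0
H -0.02431420 4.07616824 -1.24743492 adsorbate 0
O 1.38115537 2.39223127 0.22700525 adsorbate 0
H 2.88359867 3.66120631 -0.43437424 adsorbate 0
H 1.05831786 2.19937123 -2.38901141 adsorbate 0
H 2.73203884 1.72176444 -1.94363242 adsorbate 0
H 0.52987406 6.94121159 -1.25917574 adsorbate 0
H 0.47176726 4.50683436 0.97407110 adsorbate 0
O -0.48916277 4.93488390 -6.76430756 adsorbate 0
C -1.21718960 6.23695722 -6.60752109 adsorbate 0
C -0.22345764 7.35065793 -6.45863349 adsorbate 0
C 0.62630814 7.10393689 -5.24742464 adsorbate 0
C 1.35433497 5.80186357 -5.40421112 adsorbate 0
C 0.36060300 4.68816287 -5.55309872 adsorbate 0
H -1.85642836 6.19412398 -5.71335157 adsorbate 0
O -0.91766968 8.59184275 -6.30886740 adsorbate 0
H 0.41608934 7.39318861 -7.35259703 adsorbate 0
O 1.57380324 8.16558541 -5.10580733 adsorbate 0
H -0.01329074 7.06093429 -4.35352081 adsorbate 0
O 2.16415160 5.56666226 -4.24931832 adsorbate 0
H 1.99357372 5.84469681 -6.29838063 adsorbate 0
H -0.27894397 4.64563218 -4.65913518 adsorbate 0
H 0.89461227 3.73340531 -5.66830340 adsorbate 0
H -0.25670331 9.29548937 -6.21450168 adsorbate 0
H 2.11068486 7.98513634 -4.31834542 adsorbate 0
O -5.28037264 6.11853516 -6.01457251 adsorbate 0
C -5.65456833 7.57109769 -6.00827308 adsorbate 0
C -5.28742233 8.18771967 -7.32545991 adsorbate 0
C -3.80986675 8.05298174 -7.54608447 adsorbate 0
C -3.43567107 6.60041921 -7.55238390 adsorbate 0
C -3.80281706 5.98379724 -6.23519706 adsorbate 0
O -4.95239819 8.23948394 -4.95702766 adsorbate 0
H -6.73815666 7.66975975 -5.84671155 adsorbate 0
O -5.64393691 9.57255101 -7.31917491 adsorbate 0
H -5.82719148 7.67326633 -8.13415456 adsorbate 0
O -3.46007229 8.64059774 -8.80197111 adsorbate 0
H -3.27009623 8.56703087 -6.73713374 adsorbate 0
O -2.02700623 6.47215853 -7.76241388 adsorbate 0
H -3.97580194 6.08627595 -8.36103422 adsorbate 0
H -3.26304792 6.49825057 -5.42650241 adsorbate 0
H -3.52857508 4.91854235 -6.24003168 adsorbate 0
H -5.20939067 9.17469696 -4.97224161 adsorbate 0
H -5.39789643 9.94931548 -8.17848430 adsorbate 0
H -2.50270037 8.54190789 -8.92279875 adsorbate 0
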