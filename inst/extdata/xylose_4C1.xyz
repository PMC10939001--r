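20
Lattice="0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000 0.00000000" Properties=species:S:1:pos:R:3:tags:S:1:frozen:I:1 pbc="F F F"
O 1.41421356 0.00000000 0.25000000 adsorbate 0
C 0.70710678 1.22474487 -0.25000000 adsorbate 0
C -0.70710678 1.22474487 0.25000000 adsorbate 0
C -1.41421356 0.00000000 -0.25000000 adsorbate 0
C -0.70710678 -1.22474487 0.25000000 adsorbate 0
C 0.70710678 -1.22474487 -0.25000000 adsorbate 0
O 1.38115537 2.39223127 0.22700525 adsorbate 0
H 0.70696865 1.22450562 -1.34999997 adsorbate 0
O -1.38115537 2.39223127 -0.22700525 adsorbate 0
H -0.70696865 1.22450562 1.34999997 adsorbate 0
O -2.76231074 0.00000000 0.22700525 adsorbate 0
H -1.41393730 0.00000000 -1.34999997 adsorbate 0
O -1.38115537 -2.39223127 -0.22700525 adsorbate 0
H -0.70696865 -1.22450562 1.34999997 adsorbate 0
H 0.70696865 -1.22450562 -1.34999997 adsorbate 0
H 1.22560569 -2.12281133 0.11692712 adsorbate 0
H 0.90752368 3.16966606 -0.10790993 adsorbate 0
H -2.29124949 2.37077159 0.10790993 adsorbate 0
H -3.19877317 -0.79889447 -0.10790993 adsorbate 0
H -0.90752368 -3.16966606 0.10790993 adsorbate 0
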