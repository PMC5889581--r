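REMARK  synthetic fixture: altlocs, hydrogen, HETATM, water
ATOM      1  N   MET A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA AMET A   1       1.458   0.000   0.000  0.60  0.00           C
ATOM      3  CA BMET A   1       1.600   0.100   0.000  0.40  0.00           C
ATOM      4 HB1  MET A   1       2.000   1.000   0.000  1.00  0.00           H
ATOM      5  CA ASER A   2       4.000   0.000   0.000  0.50  0.00           C
ATOM      6  CA BSER A   2       4.200   0.000   0.000  0.50  0.00           C
TER       7      SER A   2
ATOM      8  N   LEU B  10       0.000   0.000   4.000  1.00  0.00           N
ATOM      9  CA  LEU B  10       1.458   0.000   4.000  1.00  0.00           C
TER      10      LEU B  10
HETATM   11 ZN    ZN B 200       8.000   8.000   8.000  1.00  0.00          ZN
HETATM   12  O   HOH B 300       9.000   9.000   9.000  1.00  0.00           O
END
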