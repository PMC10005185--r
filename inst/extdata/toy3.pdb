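REMARK  three-residue toy fixture with altlocs, an insertion code and a water
ATOM      1  N  AALA A   1      11.104   6.134  -6.504  0.60 10.00           N
ATOM      2  N  BALA A   1      11.204   6.234  -6.604  0.40 10.00           N
ATOM      3  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C
ATOM      4  CB  ALA A   1      12.451   7.301  -4.744  1.00 10.00           C
ATOM      5  N   GLY A   2A     10.217   4.962  -3.513  1.00 10.00           N
ATOM      6  CA  GLY A   2A     12.000   7.000  -4.000  1.00 10.00           C
HETATM    7  O   HOH A 101      13.000   8.000  -3.000  1.00 10.00           O
END
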