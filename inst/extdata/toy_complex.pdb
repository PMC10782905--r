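REMARK  synthetic toy protein-DNA complex for demonstrating vdW-rule labeling
ATOM      1  N   ARG A   1       2.800   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ARG A   1       3.900   0.900   0.000  1.00  0.00           C
ATOM      3  CZ  ARG A   1       3.200  -0.800   0.500  1.00  0.00           C
ATOM      4  CA  GLY A   2       8.500   2.000   1.000  1.00  0.00           C
ATOM      5  CA  LYS A   3       4.100   1.500  -1.200  1.00  0.00           C
ATOM      6  NZ  LYS A   3       3.300   0.400  -0.900  1.00  0.00           N
ATOM      7  CA  ALA A   4      15.000   5.000   3.000  1.00  0.00           C
ATOM      8  CA  TYR A   5       5.500  -2.500   0.800  1.00  0.00           C
ATOM      9  OH  TYR A   5       4.000  -1.900   0.300  1.00  0.00           O
HETATM   10  O   HOH A  90       1.000   1.000   1.000  1.00  0.00           O
ATOM     11  P    DA B   1       0.000   0.000   0.000  1.00  0.00           P
ATOM     12  O5'  DA B   1       1.200   0.800   0.300  1.00  0.00           O
ATOM     13  N1   DA B   1      -1.000  -1.200   0.400  1.00  0.00           N
END
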