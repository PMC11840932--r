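HEADER    SYNTHETIC PROTEIN-DNA TOY COMPLEX
ATOM      1 N    GLY A   1     -13.800   5.000   0.000  1.00  0.00           N
ATOM      2 N    GLY A   2     -17.600   0.000   0.000  1.00  0.00           N
ATOM      3 N    GLY A   3     -21.400   5.000   0.000  1.00  0.00           N
ATOM      4 N    GLY A   4     -25.200   0.000   0.000  1.00  0.00           N
ATOM      5 N    GLY A   5     -29.000   5.000   0.000  1.00  0.00           N
HETATM    6 FE1  SF4 A 200       0.000   0.000   0.000  1.00  0.00          FE
HETATM    7 FE2  SF4 A 200       2.300   2.300   0.000  1.00  0.00          FE
HETATM    8 FE3  SF4 A 200       2.300   0.000   2.300  1.00  0.00          FE
HETATM    9 FE4  SF4 A 200       0.000   2.300   2.300  1.00  0.00          FE
HETATM   10 S1   SF4 A 200       2.300   0.000   0.000  1.00  0.00           S
HETATM   11 S2   SF4 A 200       0.000   2.300   0.000  1.00  0.00           S
HETATM   12 S3   SF4 A 200       0.000   0.000   2.300  1.00  0.00           S
HETATM   13 S4   SF4 A 200       2.300   2.300   2.300  1.00  0.00           S
ATOM     14 P    DA  B   1       9.800   0.000   0.000  1.00  0.00           P
ATOM     15 OP1  DA  B   1      10.600   1.200   0.000  1.00  0.00           O
ATOM     16 OP2  DA  B   1      10.600  -1.200   0.000  1.00  0.00           O
ATOM     17 O5'  DA  B   1      11.200   0.000   1.100  1.00  0.00           O
ATOM     18 O3'  DA  B   1      11.000   0.000   1.300  1.00  0.00           O
ATOM     19 P    DA  B   2      16.300   0.000   0.000  1.00  0.00           P
ATOM     20 OP1  DA  B   2      17.100   1.200   0.000  1.00  0.00           O
ATOM     21 OP2  DA  B   2      17.100  -1.200   0.000  1.00  0.00           O
ATOM     22 O5'  DA  B   2      17.700   0.000   1.100  1.00  0.00           O
ATOM     23 O3'  DA  B   2      17.500   0.000   1.300  1.00  0.00           O
END
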