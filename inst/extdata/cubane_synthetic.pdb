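HEADER    SYNTHETIC IDEALIZED [4FE4S] CUBANE
ATOM      1 SG   CYS A   1      -1.328  -1.328  -1.328  1.00  0.00           S
ATOM      2 SG   CYS A   2       3.628   3.628  -1.328  1.00  0.00           S
ATOM      3 SG   CYS A   3       3.628  -1.328   3.628  1.00  0.00           S
ATOM      4 SG   CYS A   4      -1.328   3.628   3.628  1.00  0.00           S
HETATM    5 FE1  SF4 A 100       0.000   0.000   0.000  1.00  0.00          FE
HETATM    6 FE2  SF4 A 100       2.300   2.300   0.000  1.00  0.00          FE
HETATM    7 FE3  SF4 A 100       2.300   0.000   2.300  1.00  0.00          FE
HETATM    8 FE4  SF4 A 100       0.000   2.300   2.300  1.00  0.00          FE
HETATM    9 S1   SF4 A 100       2.300   0.000   0.000  1.00  0.00           S
HETATM   10 S2   SF4 A 100       0.000   2.300   0.000  1.00  0.00           S
HETATM   11 S3   SF4 A 100       0.000   0.000   2.300  1.00  0.00           S
HETATM   12 S4   SF4 A 100       2.300   2.300   2.300  1.00  0.00           S
END
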