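ATOM      1 N    ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2 CA   ALA A   1       1.470   0.000   0.000  1.00  0.00           C
ATOM      3 C    ALA A   1       2.200   1.200   0.000  1.00  0.00           C
ATOM      4 O    ALA A   1       1.900   2.300   0.000  1.00  0.00           O
ATOM      5 CB   ALA A   1       1.800  -1.400   0.000  1.00  0.00           C
ATOM      6 N    ALA A   2       3.300   0.000   0.000  1.00  0.00           N
ATOM      7 CA   ALA A   2       4.770   0.000   0.000  1.00  0.00           C
ATOM      8 C    ALA A   2       5.500   1.200   0.000  1.00  0.00           C
ATOM      9 O    ALA A   2       5.200   2.300   0.000  1.00  0.00           O
ATOM     10 CB   ALA A   2       5.100  -1.400   0.000  1.00  0.00           C
ATOM     11 N    ALA A   3       6.600   0.000   0.000  1.00  0.00           N
ATOM     12 CA   ALA A   3       8.070   0.000   0.000  1.00  0.00           C
ATOM     13 C    ALA A   3       8.800   1.200   0.000  1.00  0.00           C
ATOM     14 O    ALA A   3       8.500   2.300   0.000  1.00  0.00           O
ATOM     15 CB   ALA A   3       8.400  -1.400   0.000  1.00  0.00           C
HETATM   16 C1   LIG A 900       5.100  -4.500   0.500  1.00  0.00           C
HETATM   17 N1   LIG A 900       6.200  -4.000   0.200  1.00  0.00           N
HETATM   18 O1   LIG A 900       4.100  -3.900   0.900  1.00  0.00           O
HETATM   19 O    HOH A1001       5.500  -6.500   1.200  1.00  0.00           O
END
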