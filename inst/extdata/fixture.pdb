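ATOM      1  N   VAL A   1       0.000   0.000   5.000  1.00  0.00           N
ATOM      2  CA  VAL A   1       1.500   0.000   5.000  1.00  0.00           C
ATOM      3  C   VAL A   1       3.000   0.000   5.000  1.00  0.00           C
ATOM      4  O   VAL A   1       3.000   1.200   5.000  1.00  0.00           O
ATOM      5  CB  VAL A   1       0.000   0.000   0.000  1.00  0.00           C
ATOM      6  CG1 VAL A   1       1.000   0.000   0.000  1.00  0.00           C
ATOM      7  CG2 VAL A   1       2.000   0.000   0.000  1.00  0.00           C
ATOM      8  N   VAL A   2      10.000   2.000   5.000  1.00  0.00           N
ATOM      9  CA  VAL A   2      11.500   2.000   5.000  1.00  0.00           C
ATOM     10  C   VAL A   2      13.000   2.000   5.000  1.00  0.00           C
ATOM     11  O   VAL A   2      13.000   3.200   5.000  1.00  0.00           O
ATOM     12  CB  VAL A   2       0.000   2.000   0.000  1.00  0.00           C
ATOM     13  CG1 VAL A   2       1.000   2.000   0.000  1.00  0.00           C
ATOM     14  CG2 VAL A   2       2.000   2.000   0.000  1.00  0.00           C
ATOM     15  N   VAL A   3     -10.000   4.450   5.000  1.00  0.00           N
ATOM     16  CA  VAL A   3      -8.500   4.450   5.000  1.00  0.00           C
ATOM     17  C   VAL A   3      -7.000   4.450   5.000  1.00  0.00           C
ATOM     18  O   VAL A   3      -7.000   5.650   5.000  1.00  0.00           O
ATOM     19  CB  VAL A   3       0.000   4.450   0.000  1.00  0.00           C
ATOM     20  CG1 VAL A   3       1.000   4.450   0.000  1.00  0.00           C
ATOM     21  CG2 VAL A   3       2.000   4.450   0.000  1.00  0.00           C
ATOM     22  N   ALA A   4      50.000   0.000   5.000  1.00  0.00           N
ATOM     23  CA  ALA A   4      51.500   0.000   5.000  1.00  0.00           C
ATOM     24  C   ALA A   4      53.000   0.000   5.000  1.00  0.00           C
ATOM     25  O   ALA A   4      53.000   1.200   5.000  1.00  0.00           O
ATOM     26  CB  ALA A   4      50.000   0.000   0.000  1.00  0.00           C
ATOM     27  N   ALA A   5      10.000   8.900   5.000  1.00  0.00           N
ATOM     28  CA  ALA A   5      11.500   8.900   5.000  1.00  0.00           C
ATOM     29  C   ALA A   5      13.000   8.900   5.000  1.00  0.00           C
ATOM     30  O   ALA A   5      13.000  10.100   5.000  1.00  0.00           O
ATOM     31  CB  ALA A   5       0.000   8.900   0.000  1.00  0.00           C
ATOM     32  N   GLY A   6      60.000   0.000   5.000  1.00  0.00           N
ATOM     33  CA  GLY A   6      61.500   0.000   5.000  1.00  0.00           C
ATOM     34  C   GLY A   6      63.000   0.000   5.000  1.00  0.00           C
ATOM     35  O   GLY A   6      63.000   1.200   5.000  1.00  0.00           O
END
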