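CRYST1   20.000   20.000   25.000  90.00  90.00  90.00 P 21 21 21    1
ATOM      1  N   CYS A   1       4.000   2.000   2.000  1.00 20.00           N
ATOM      2  CA  CYS A   1       5.400   2.400   2.200  1.00 20.00           C
ATOM      3  C   CYS A   1       6.300   1.200   2.500  1.00 20.00           C
ATOM      4  O   CYS A   1       5.900   0.050   2.400  1.00 20.00           O
ATOM      5  CB  CYS A   1       5.950   3.400   1.150  1.00 20.00           C
ATOM      6  N1  FMN A   2       8.500   4.500   3.600  1.00 20.00           N
ATOM      7  C2  FMN A   2       9.600   5.200   3.200  1.00 20.00           C
ATOM      8  C4  FMN A   2       9.800   3.600   4.600  1.00 20.00           C
ATOM      9  O2  FMN A   2      10.700   4.900   2.400  1.00 20.00           O
ATOM     10  SG CCYS A   1       7.400   4.100   0.600  0.65 20.00           S
ATOM     11  CD1CCYS A   1       8.300   5.300   1.400  0.65 20.00           C
ATOM     12  CD2CCYS A   1       8.900   2.900   0.900  0.65 20.00           C
ATOM     13  SG ACYS A   1       5.100   4.900   0.200  0.35 20.00           S
ATOM     14  CD1ACYS A   1       3.800   5.800   0.800  0.35 20.00           C
ATOM     15  CD2ACYS A   1       4.600   5.500   1.900  0.35 20.00           C
END
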