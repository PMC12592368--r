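ATOM      1  N   ASP A 101      13.540   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ASP A 101      15.000   0.000   0.000  1.00  0.00           C
ATOM      3  C   ASP A 101      15.520   1.430   0.000  1.00  0.00           C
ATOM      4  O   ASP A 101      15.950   2.580   0.000  1.00  0.00           O
ATOM      5  CB  ASP A 101      15.510  -0.510   1.340  1.00  0.00           C
ATOM      6  CG  ASP A 101      16.012  -1.012   2.684  1.00  0.00           C
ATOM      7  OD1 ASP A 101      17.112  -1.012   3.234  1.00  0.00           O
ATOM      8  OD2 ASP A 101      14.912  -1.012   3.234  1.00  0.00           O
ATOM      9  N   GLU A 102      13.540   0.000  11.500  1.00  0.00           N
ATOM     10  CA  GLU A 102      15.000   0.000  11.500  1.00  0.00           C
ATOM     11  C   GLU A 102      15.520   1.430  11.500  1.00  0.00           C
ATOM     12  O   GLU A 102      15.950   2.580  11.500  1.00  0.00           O
ATOM     13  CB  GLU A 102      15.510  -0.510  12.840  1.00  0.00           C
ATOM     14  CG  GLU A 102      16.012  -1.012  14.184  1.00  0.00           C
ATOM     15  CD  GLU A 102      16.514  -1.514  15.528  1.00  0.00           C
ATOM     16  OE1 GLU A 102      17.614  -1.514  16.078  1.00  0.00           O
ATOM     17  OE2 GLU A 102      15.414  -1.514  16.078  1.00  0.00           O
END
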