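REMARK  synthetic side-chain fixture: Arg/Asp salt-bridge pair, Ser/Asn
REMARK  hydrogen-bond pair, and a remote Ala; one MAN ligand HETATM
ATOM      1  N   ARG A 641       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ARG A 641       1.500   0.000   0.000  1.00  0.00           C
ATOM      3  CB  ARG A 641       2.200   1.300   0.000  1.00  0.00           C
ATOM      4  NE  ARG A 641       3.600   1.300   0.000  1.00  0.00           N
ATOM      5  NH1 ARG A 641       4.600   2.100   0.000  1.00  0.00           N
ATOM      6  N   ASP A 709       9.000   2.100   0.000  1.00  0.00           N
ATOM      7  CA  ASP A 709       8.300   3.100   0.000  1.00  0.00           C
ATOM      8  CB  ASP A 709       7.600   3.100   1.200  1.00  0.00           C
ATOM      9  OD1 ASP A 709       7.800   2.100   0.000  1.00  0.00           O
ATOM     10  OD2 ASP A 709       7.400   4.200   1.800  1.00  0.00           O
ATOM     11  N   SER A 505      20.000   0.000   0.000  1.00  0.00           N
ATOM     12  CA  SER A 505      21.500   0.000   0.000  1.00  0.00           C
ATOM     13  OG  SER A 505      22.200   1.200   0.000  1.00  0.00           O
ATOM     14  N   ASN A 455      26.000   1.200   0.000  1.00  0.00           N
ATOM     15  CA  ASN A 455      25.800   2.500   0.000  1.00  0.00           C
ATOM     16  OD1 ASN A 455      25.100   1.200   0.000  1.00  0.00           O
ATOM     17  ND2 ASN A 455      26.500   3.500   0.000  1.00  0.00           N
ATOM     18  N   ALA A 100      50.000  50.000  50.000  1.00  0.00           N
ATOM     19  CA  ALA A 100      51.500  50.000  50.000  1.00  0.00           C
ATOM     20  CB  ALA A 100      52.200  51.300  50.000  1.00  0.00           C
HETATM   21  C1  MAN A 901      30.000  30.000  30.000  1.00  0.00           C
END
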