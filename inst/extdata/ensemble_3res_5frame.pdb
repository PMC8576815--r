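MODEL        1
ATOM      1  CA  ALA A   1       0.548   0.253   0.605  1.00  0.00           C
ATOM      2  CA  GLY A   2       3.574   0.162  -0.038  1.00  0.00           C
ATOM      3  CA  SER A   3       5.645   3.158   1.907  1.00  0.00           C
ENDMDL
MODEL        2
ATOM      1  CA  ALA A   1      -0.025  -0.556   0.254  1.00  0.00           C
ATOM      2  CA  GLY A   2       4.322  -0.112  -0.114  1.00  0.00           C
ATOM      3  CA  SER A   3       6.415   3.147   0.037  1.00  0.00           C
ENDMDL
MODEL        3
ATOM      1  CA  ALA A   1      -0.976  -0.713   0.758  1.00  0.00           C
ATOM      2  CA  GLY A   2       4.328  -0.069  -0.172  1.00  0.00           C
ATOM      3  CA  SER A   3       5.377   3.686   0.997  1.00  0.00           C
ENDMDL
MODEL        4
ATOM      1  CA  ALA A   1      -0.705   0.182  -0.244  1.00  0.00           C
ATOM      2  CA  GLY A   2       3.984   0.282   0.202  1.00  0.00           C
ATOM      3  CA  SER A   3       5.244   3.614   0.413  1.00  0.00           C
ENDMDL
MODEL        5
ATOM      1  CA  ALA A   1      -0.314   0.014   0.303  1.00  0.00           C
ATOM      2  CA  GLY A   2       3.460   0.082  -0.291  1.00  0.00           C
ATOM      3  CA  SER A   3       4.534   3.056   0.553  1.00  0.00           C
ENDMDL
END
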