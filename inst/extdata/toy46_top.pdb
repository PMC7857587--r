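ATOM      1  N   ROT A   1      -1.458   0.000   0.000  1.00  0.00           N  
ATOM      2  CA  ROT A   1       0.000   0.000   0.000  1.00  0.00           C  
ATOM      3  C   ROT A   1       0.546   1.424   0.000  1.00  0.00           C  
ATOM      4  CB  ROT A   1      -0.606   0.143   1.397  1.00  0.00           C  
ATOM      5  CG  ROT A   1      -1.585   0.374   3.653  1.00  0.00           C  
ATOM      6  N1  ROT A   1      -2.774   0.655   6.393  1.00  0.00           N  
ATOM      7  O1  ROT A   1      -3.270   0.772   7.535  1.00  0.00           O  
END   
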