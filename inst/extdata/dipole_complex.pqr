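ATOM      1 CB   GLY  A 1    -2.2000     0.0000     0.0000   0.0000  1.8000
ATOM      2 NZ   LYS  A 2    -3.9889     0.0000     0.0000   1.0000  1.8000
ATOM      3 CA   GLY  A 3    -9.1820    -2.6852    -2.0478   0.0000  1.8000
ATOM      4 CA   GLY  A 4    -6.9256     2.7281     4.9670   0.0000  1.8000
ATOM      5 CA   GLY  A 5    -6.5580    -4.0370     4.0602   0.0000  1.8000
ATOM      6 CA   GLY  A 6    -7.9500    -0.4655     4.8874   0.0000  1.8000
ATOM      7 CA   GLY  A 7   -12.3361    -4.1530    -4.3435   0.0000  1.8000
ATOM      8 CA   GLY  A 8    -8.7205     0.6067     1.2704   0.0000  1.8000
ATOM      9 CA   GLY  A 9   -13.7765    -4.9130    -0.0952   0.0000  1.8000
ATOM     10 CA   GLY  A 10    -7.3268     4.8574     4.7102   0.0000  1.8000
ATOM     11 CA   GLY  A 11    -9.6728    -1.8342    -1.3778   0.0000  1.8000
ATOM     12 CA   GLY  A 12    -7.3740     1.3945     1.7999   0.0000  1.8000
ATOM     13 CB   GLY  B 1     2.2000     0.0000     0.0000   0.0000  1.8000
ATOM     14 OD1  ASP  B 2     3.6988     0.0000     0.0000  -1.0000  1.8000
ATOM     15 CA   GLY  B 3     8.5765    -3.8886    -0.1843   0.0000  1.8000
ATOM     16 CA   GLY  B 4    10.9224     3.9444     2.2177   0.0000  1.8000
ATOM     17 CA   GLY  B 5     6.1349    -2.0133     4.3014   0.0000  1.8000
ATOM     18 CA   GLY  B 6    13.2127    -0.2278     0.9970   0.0000  1.8000
ATOM     19 CA   GLY  B 7     9.3972     4.0552     2.0051   0.0000  1.8000
ATOM     20 CA   GLY  B 8    10.0379    -3.6013     3.4403   0.0000  1.8000
ATOM     21 CA   GLY  B 9    13.7318    -4.7225    -0.8587   0.0000  1.8000
ATOM     22 CA   GLY  B 10     7.5258     4.6356    -1.9499   0.0000  1.8000
ATOM     23 CA   GLY  B 11    10.8797     0.8599    -2.6367   0.0000  1.8000
ATOM     24 CA   GLY  B 12    10.9252     3.6846     0.3669   0.0000  1.8000
END
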