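ATOM      1 CA   GLY  A 1     7.9889    -0.3341     0.1213   0.0000  1.8000
ATOM      2 CA   GLY  A 2     5.2010     5.2624    -0.9826   0.0000  1.8000
ATOM      3 CA   GLY  A 3    -0.3843     7.1717     0.9715   0.0000  1.8000
ATOM      4 CA   GLY  A 4    -5.7336     5.0348    -0.3668   0.0000  1.8000
ATOM      5 CA   GLY  A 5    -7.7563     0.2728     0.2789   0.0000  1.8000
ATOM      6 CA   GLY  A 6    -5.0113    -5.7070    -0.4096   0.0000  1.8000
ATOM      7 CA   GLY  A 7    -0.1599    -7.5466     0.9934   0.0000  1.8000
ATOM      8 CA   GLY  A 8     5.7754    -5.7186     0.8120   0.0000  1.8000
ATOM      9 OG   SER  A 9    20.0311    11.4664     0.9715  -0.5000  1.8000
ATOM     10 CA   GLY  A 10     4.6831   -20.0610    -1.1341   0.0000  1.8000
ATOM     11 OG   SER  A 11    16.9500    11.3793    -3.7590  -0.5000  1.8000
ATOM     12 OG   SER  A 12    16.1854     6.3745   -19.4540  -0.5000  1.8000
ATOM     13 OG   SER  A 13   -13.2560    11.1571    14.7942   0.5000  1.8000
ATOM     14 OG   SER  A 14    -5.5561    10.6979   -19.9792  -0.5000  1.8000
ATOM     15 CA   GLY  A 15    -0.1105   -22.5172    -3.2592   0.0000  1.8000
ATOM     16 OG   SER  A 16    18.4761    -5.1617     5.8896   0.5000  1.8000
ATOM     17 OG   SER  A 17    13.3475   -13.8418    19.3684   0.5000  1.8000
ATOM     18 CA   GLY  A 18    12.3449    12.5789   -12.2395   0.0000  1.8000
END
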