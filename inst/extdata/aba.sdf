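ABA
     RDKit          3D

 19 19  0  0  0  0  0  0  0  0999 V2000
   -1.7363   -2.8195   -0.2535 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1357   -1.4025   -0.3677 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4303   -1.1270   -0.2996 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9189    0.2608   -0.4042 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1377    0.5205   -0.5994 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9326    1.3890   -0.2737 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6659    0.8362    0.3638 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6583    1.9363    0.4348 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0271    0.2788    1.7414 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1987   -0.2947   -0.5497 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2604    0.1638   -1.8639 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.2106   -0.6679   -0.2750 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1634    0.1723   -0.0077 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5551   -0.1837    0.2645 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0442   -1.5843    0.2650 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3919    0.8112    0.5183 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.8132    0.5795    0.8061 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.6072    1.7057    1.0606 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.3164   -0.5745    0.8281 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  2  0
  4  6  1  0
  6  7  1  0
  7  8  1  0
  7  9  1  0
  7 10  1  0
 10 11  1  0
 10 12  1  0
 12 13  2  0
 13 14  1  0
 14 15  1  0
 14 16  2  0
 16 17  1  0
 17 18  1  0
 17 19  2  0
 10  2  1  0
M  END
$$$$
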