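sulfobactin
     RDKit          3D

 24 26  0  0  0  0  0  0  0  0999 V2000
   -5.4961    0.6577    1.7933 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4309    0.3831    1.1566 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.0256   -0.9401    1.1911 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8611   -1.2935    0.5072 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4129   -2.7045    0.5336 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1651   -0.3165   -0.1715 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0094   -0.6845   -0.8464 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2989    0.2913   -1.5343 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1633   -0.1929   -2.3840 S   0  0  0  0  0  0  0  0  0  0  0  0
    0.9950   -1.5961   -2.8495 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.3888    0.7563   -3.5253 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.4669   -0.0186   -1.2582 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.3118   -0.8612   -0.1128 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5075   -0.6027    0.7663 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4612    0.3801    1.7249 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.5286    0.6570    2.5556 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.6708   -0.0948    2.3966 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.7343   -1.0855    1.4390 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.6516   -1.3592    0.6035 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7379    1.6020   -1.5440 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8958    1.9900   -0.8723 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5978    0.9946   -0.1854 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.7365    1.3288    0.4860 N   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2121    2.7092    0.4845 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  4  6  1  0
  6  7  2  0
  7  8  1  0
  8  9  1  0
  9 10  2  0
  9 11  2  0
  9 12  1  0
 12 13  1  0
 13 14  1  0
 14 15  2  0
 15 16  1  0
 16 17  2  0
 17 18  1  0
 18 19  2  0
  8 20  2  0
 20 21  1  0
 21 22  2  0
 22 23  1  0
 23 24  1  0
 23  2  1  0
 22  6  1  0
 19 14  1  0
M  END
$$$$
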