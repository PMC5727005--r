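murf_mock
  isoswap

 27 30  0  0  0  0  0  0  0  0999 V2000
    2.5257   -1.1245    0.0000 S   0  0  0  0  0  0  0  0  0  0  0  0
    3.3427    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5257    1.1245    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2038    0.6950    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    1.3900    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2038    0.6950    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2038   -0.6950    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -1.3900    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2038   -0.6950    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.1127    0.0000    0.0000 S   0  0  0  0  0  0  0  0  0  0  0  0
    5.3527    1.1600    0.8000 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.3527   -1.1600    0.8000 O   0  0  0  0  0  0  0  0  0  0  0  0
    6.7127    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    8.1227    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    8.8177   -1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   10.2077   -1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   10.9027   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   10.2077    1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    8.8177    1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.9577    0.2858    0.0000 Cl  0  0  0  0  0  0  0  0  0  0  0  0
   11.0677    0.2858    0.0000 Cl  0  0  0  0  0  0  0  0  0  0  0  0
   12.3127   -0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   13.0377   -1.2557    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   14.4877   -1.2557    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   15.2127   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   14.4877    1.2557    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   13.0377    1.2557    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  4  0
  2  3  4  0
  3  4  4  0
  4  5  4  0
  5  6  4  0
  6  7  4  0
  7  8  4  0
  8  9  4  0
  9  1  4  0
  4  9  4  0
  2 10  1  0
 10 11  2  0
 10 12  2  0
 10 13  1  0
 13 14  1  0
 15 20  1  0
 16 21  1  0
 17 22  1  0
 22 23  1  0
 23 24  1  0
 24 25  1  0
 25 26  1  0
 26 27  1  0
 27 22  1  0
 14 15  4  0
 15 16  4  0
 16 17  4  0
 17 18  4  0
 18 19  4  0
 19 14  4  0
M  END
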