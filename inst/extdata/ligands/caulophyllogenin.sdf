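caulophyllogenin
     RDKit          2D

 35 39  0  0  0  0  0  0  0  0999 V2000
   -5.2145   -3.3115    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.3986   -1.8229    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.8327   -2.2627    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.0808   -0.4870    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.2650    0.7717    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.7670    0.6946    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4491    2.0305    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6333    3.2892    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -5.9472    2.1077    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9511    1.9533    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4531    1.8761    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6373    3.1349    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7709    0.5402    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0888   -0.7957    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5868   -0.7185    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9046   -2.0544    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5934   -2.1316    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4092   -0.8728    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7271    0.4631    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0449    1.7990    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5429    1.7218    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0409    1.6446    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.7231    0.3087    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9073   -0.9500    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0914   -2.2087    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5894   -2.2859    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0875   -2.3631    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.9033   -1.1043    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.4013   -1.1815    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.2211    0.2316    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0370    1.7202    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.6552    0.6714    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.9913    2.1333    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0848   -0.6413    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9006   -1.9001    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  2  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  7  8  1  0
  7  9  2  0
  6 10  1  0
 10 11  1  0
 11 12  1  0
 11 13  1  0
 13 14  1  0
 13 15  1  0
 15 16  2  0
 16 17  1  0
 17 18  1  0
 18 19  1  0
 19 20  1  0
 19 21  1  0
 21 22  1  0
 22 23  1  0
 23 24  1  0
 24 25  1  0
 24 26  1  0
 26 27  1  0
 27 28  1  0
 28 29  1  0
 28 30  1  0
 30 31  1  0
 30 32  1  0
 32 33  1  0
 15 34  1  0
 34 35  1  0
 35  2  1  0
 34  6  1  0
 19 13  1  0
 30 23  1  0
 24 18  1  0
M  END
$$$$
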