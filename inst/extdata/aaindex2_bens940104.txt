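H BENS940104
D Genetic code matrix (Benner et al., 1994)
R PMID:7700864
A Benner, S.A., Cohen, M.A. and Gonnet, G.H.
T Amino acid substitution during functionally constrained divergent
  evolution of protein sequences
J Protein Engineering 7, 1323-1332 (1994)
M rows = ARNDCQEGHILKMFPSTWYV, cols = ARNDCQEGHILKMFPSTWYV
    4.0
   -1.6    2.9
   -1.7   -1.5    4.7
    1.0   -2.3    1.7    4.8
   -1.9    0.7   -1.5   -1.6    5.5
   -2.1    0.3    0.4    0.3   -3.1    5.5
    1.3   -2.0    0.3    3.8   -3.0    2.0    5.7
    1.2    0.8   -2.6    1.1    1.0   -2.1    1.4    4.2
   -2.1    3.6    1.8    1.7   -1.6    3.6    0.3   -2.2    4.7
   -1.8   -1.2    0.9   -2.1   -1.9   -1.9   -2.3   -2.5   -1.8    4.1
   -2.3   -0.4   -2.2   -2.4   -1.3    0.1   -2.5   -2.2   -0.1    1.2    3.4
   -1.9   -0.2    3.5    0.3   -3.2    2.2    2.0   -2.2    0.6    0.7   -2.0    5.6
   -2.0   -0.4    0.1   -2.5   -2.7   -1.2   -1.8   -2.3   -1.8    3.3    1.5    1.6    5.4
   -2.4   -1.5   -1.3   -1.7    1.8   -2.1   -2.9   -1.9   -1.1    1.3    2.2   -2.8    0.5    4.5
    0.8    0.3   -1.6   -2.2   -1.9    1.0   -2.1   -1.8    0.7   -1.6    0.0   -1.5   -1.4   -1.8    3.8
    0.1    0.3   -0.3   -2.1    1.5   -2.3   -2.8   -0.6   -1.6   -0.5   -1.2   -1.5   -1.3    0.0    0.4    2.6
    0.9   -0.6    0.9   -2.1   -1.9   -1.7   -2.1   -2.1   -1.8    0.8   -1.9    1.0    0.7   -2.1    1.1    1.0    4.0
   -2.2    1.8   -3.0   -2.9    4.1   -2.3   -3.2    1.4   -2.1   -2.2   -0.3   -3.0   -2.0    0.0   -1.6    0.8   -2.2    7.5
   -2.4   -1.9    2.5    2.3    2.6   -0.8   -0.9   -1.8    2.3   -1.6   -1.6   -0.8   -2.9    2.0   -2.3    0.3   -2.1   -0.5    6.5
    1.0   -2.1   -2.2    1.0   -2.2   -2.0    1.3    1.1   -2.1    1.0    1.1   -2.1    1.0    1.0   -2.1   -2.2   -2.2   -2.1   -2.2    4.1
//
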