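H HELX_SYN01
D SYNTHETIC helix-class substitution similarity derived from Chou-Fasman
  alpha-helix propensities (CHOP780201); stand-in built for this package,
  not an AAindex release entry
R none
A gpcrstab authors
T Synthetic alpha-helix substitution similarity table
J unpublished (constructed from published CHOP780201 propensities)
M rows = ARNDCQEGHILKMFPSTWYV, cols = ARNDCQEGHILKMFPSTWYV
   2.00
   1.12   2.00
   0.50   1.38   2.00
   1.18   1.94   1.32   2.00
   0.56   1.44   1.94   1.38   2.00
   1.38   1.74   1.12   1.80   1.18   2.00
   1.82   0.94   0.32   1.00   0.38   1.20   2.00
   0.30   1.18   1.80   1.12   1.74   0.92   0.12   2.00
   1.16   1.96   1.34   1.98   1.40   1.78   0.98   1.14   2.00
   1.32   1.80   1.18   1.86   1.24   1.94   1.14   0.98   1.84   2.00
   1.58   1.54   0.92   1.60   0.98   1.80   1.40   0.72   1.58   1.74   2.00
   1.48   1.64   1.02   1.70   1.08   1.90   1.30   0.82   1.68   1.84   1.90   2.00
   1.94   1.06   0.44   1.12   0.50   1.32   1.88   0.24   1.10   1.26   1.52   1.42   2.00
   1.42   1.70   1.08   1.76   1.14   1.96   1.24   0.88   1.74   1.90   1.84   1.94   1.36   2.00
   0.30   1.18   1.80   1.12   1.74   0.92   0.12   2.00   1.14   0.98   0.72   0.82   0.24   0.88   2.00
   0.70   1.58   1.80   1.52   1.86   1.32   0.52   1.60   1.54   1.38   1.12   1.22   0.64   1.28   1.60   2.00
   0.82   1.70   1.68   1.64   1.74   1.44   0.64   1.48   1.66   1.50   1.24   1.34   0.76   1.40   1.48   1.88   2.00
   1.32   1.80   1.18   1.86   1.24   1.94   1.14   0.98   1.84   2.00   1.74   1.84   1.26   1.90   0.98   1.38   1.50   2.00
   0.54   1.42   1.96   1.36   1.98   1.16   0.36   1.76   1.38   1.22   0.96   1.06   0.48   1.12   1.76   1.84   1.72   1.22   2.00
   1.28   1.84   1.22   1.90   1.28   1.90   1.10   1.02   1.88   1.96   1.70   1.80   1.22   1.86   1.02   1.42   1.54   1.96   1.26   2.00
//
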