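REMARK   ideal A-form RNA nucleotide templates (synthetic)
REMARK   pair-frame coordinates; WC partner = 180 deg rotation about x
REMARK   helix placement: twist 32.700 deg, rise 2.810 A,
REMARK   x-displacement -4.5900 A, inclination 25.9697 deg
ATOM      1  P     A A   1       1.253   9.161   0.294  1.00  0.00           P
ATOM      2  OP1   A A   1       0.978  10.389   1.083  1.00  0.00           O
ATOM      3  OP2   A A   1       2.403   8.416   0.867  1.00  0.00           O
ATOM      4  O5'   A A   1      -0.035   8.227   0.368  1.00  0.00           O
ATOM      5  C5'   A A   1      -1.341   8.741   0.042  1.00  0.00           C
ATOM      6  C4'   A A   1      -2.389   7.677   0.263  1.00  0.00           C
ATOM      7  O4'   A A   1      -2.201   6.578  -0.656  1.00  0.00           O
ATOM      8  C3'   A A   1      -2.242   7.061   1.633  1.00  0.00           C
ATOM      9  O3'   A A   1      -2.934   7.823   2.617  1.00  0.00           O
ATOM     10  C2'   A A   1      -2.883   5.691   1.445  1.00  0.00           C
ATOM     11  O2'   A A   1      -4.288   5.758   1.584  1.00  0.00           O
ATOM     12  C1'   A A   1      -2.479   5.346   0.000  1.00  0.00           C
ATOM     13  N9    A A   1      -1.291   4.498   0.000  1.00  0.00           N
ATOM     14  C8    A A   1       0.024   4.897   0.000  1.00  0.00           C
ATOM     15  N7    A A   1       0.877   3.902   0.000  1.00  0.00           N
ATOM     16  C5    A A   1       0.071   2.771   0.000  1.00  0.00           C
ATOM     17  C6    A A   1       0.369   1.398   0.000  1.00  0.00           C
ATOM     18  N6    A A   1       1.611   0.909   0.000  1.00  0.00           N
ATOM     19  N1    A A   1      -0.668   0.532   0.000  1.00  0.00           N
ATOM     20  C2    A A   1      -1.912   1.023   0.000  1.00  0.00           C
ATOM     21  N3    A A   1      -2.320   2.290   0.000  1.00  0.00           N
ATOM     22  C4    A A   1      -1.267   3.124   0.000  1.00  0.00           C
ATOM     23  P     C A   2       1.276   9.201   0.236  1.00  0.00           P
ATOM     24  OP1   C A   2       1.012  10.437   1.016  1.00  0.00           O
ATOM     25  OP2   C A   2       2.426   8.455   0.808  1.00  0.00           O
ATOM     26  O5'   C A   2      -0.017   8.274   0.326  1.00  0.00           O
ATOM     27  C5'   C A   2      -1.321   8.791   0.004  1.00  0.00           C
ATOM     28  C4'   C A   2      -2.374   7.735   0.241  1.00  0.00           C
ATOM     29  O4'   C A   2      -2.197   6.627  -0.669  1.00  0.00           O
ATOM     30  C3'   C A   2      -2.221   7.131   1.616  1.00  0.00           C
ATOM     31  O3'   C A   2      -2.903   7.904   2.597  1.00  0.00           O
ATOM     32  C2'   C A   2      -2.870   5.762   1.445  1.00  0.00           C
ATOM     33  O2'   C A   2      -4.274   5.837   1.591  1.00  0.00           O
ATOM     34  C1'   C A   2      -2.477   5.402   0.000  1.00  0.00           C
ATOM     35  N1    C A   2      -1.285   4.542   0.000  1.00  0.00           N
ATOM     36  C2    C A   2      -1.472   3.158   0.000  1.00  0.00           C
ATOM     37  O2    C A   2      -2.628   2.709   0.000  1.00  0.00           O
ATOM     38  N3    C A   2      -0.391   2.344   0.000  1.00  0.00           N
ATOM     39  C4    C A   2       0.837   2.868   0.000  1.00  0.00           C
ATOM     40  N4    C A   2       1.875   2.027   0.000  1.00  0.00           N
ATOM     41  C5    C A   2       1.056   4.275   0.000  1.00  0.00           C
ATOM     42  C6    C A   2      -0.023   5.068   0.000  1.00  0.00           C
ATOM     43  P     G A   3       1.255   9.214   0.294  1.00  0.00           P
ATOM     44  OP1   G A   3       0.980  10.442   1.083  1.00  0.00           O
ATOM     45  OP2   G A   3       2.405   8.469   0.867  1.00  0.00           O
ATOM     46  O5'   G A   3      -0.033   8.280   0.368  1.00  0.00           O
ATOM     47  C5'   G A   3      -1.339   8.794   0.042  1.00  0.00           C
ATOM     48  C4'   G A   3      -2.387   7.730   0.263  1.00  0.00           C
ATOM     49  O4'   G A   3      -2.199   6.631  -0.656  1.00  0.00           O
ATOM     50  C3'   G A   3      -2.240   7.114   1.633  1.00  0.00           C
ATOM     51  O3'   G A   3      -2.932   7.876   2.617  1.00  0.00           O
ATOM     52  C2'   G A   3      -2.881   5.744   1.445  1.00  0.00           C
ATOM     53  O2'   G A   3      -4.286   5.811   1.584  1.00  0.00           O
ATOM     54  C1'   G A   3      -2.477   5.399   0.000  1.00  0.00           C
ATOM     55  N9    G A   3      -1.289   4.551   0.000  1.00  0.00           N
ATOM     56  C8    G A   3       0.023   4.962   0.000  1.00  0.00           C
ATOM     57  N7    G A   3       0.870   3.969   0.000  1.00  0.00           N
ATOM     58  C5    G A   3       0.071   2.833   0.000  1.00  0.00           C
ATOM     59  C6    G A   3       0.424   1.460   0.000  1.00  0.00           C
ATOM     60  O6    G A   3       1.554   0.955   0.000  1.00  0.00           O
ATOM     61  N1    G A   3      -0.700   0.641   0.000  1.00  0.00           N
ATOM     62  C2    G A   3      -1.999   1.087   0.000  1.00  0.00           C
ATOM     63  N2    G A   3      -2.949   0.139   0.000  1.00  0.00           N
ATOM     64  N3    G A   3      -2.342   2.364   0.000  1.00  0.00           N
ATOM     65  C4    G A   3      -1.265   3.177   0.000  1.00  0.00           C
ATOM     66  P     U A   4       1.250   9.170   0.297  1.00  0.00           P
ATOM     67  OP1   U A   4       0.975  10.398   1.086  1.00  0.00           O
ATOM     68  OP2   U A   4       2.400   8.425   0.869  1.00  0.00           O
ATOM     69  O5'   U A   4      -0.038   8.236   0.369  1.00  0.00           O
ATOM     70  C5'   U A   4      -1.343   8.749   0.044  1.00  0.00           C
ATOM     71  C4'   U A   4      -2.392   7.685   0.264  1.00  0.00           C
ATOM     72  O4'   U A   4      -2.203   6.586  -0.655  1.00  0.00           O
ATOM     73  C3'   U A   4      -2.245   7.069   1.634  1.00  0.00           C
ATOM     74  O3'   U A   4      -2.937   7.829   2.618  1.00  0.00           O
ATOM     75  C2'   U A   4      -2.886   5.698   1.445  1.00  0.00           C
ATOM     76  O2'   U A   4      -4.290   5.765   1.583  1.00  0.00           O
ATOM     77  C1'   U A   4      -2.481   5.354   0.000  1.00  0.00           C
ATOM     78  N1    U A   4      -1.284   4.500   0.000  1.00  0.00           N
ATOM     79  C2    U A   4      -1.462   3.131   0.000  1.00  0.00           C
ATOM     80  O2    U A   4      -2.563   2.608   0.000  1.00  0.00           O
ATOM     81  N3    U A   4      -0.302   2.397   0.000  1.00  0.00           N
ATOM     82  C4    U A   4       0.989   2.884   0.000  1.00  0.00           C
ATOM     83  O4    U A   4       1.935   2.094   0.000  1.00  0.00           O
ATOM     84  C5    U A   4       1.089   4.311   0.000  1.00  0.00           C
ATOM     85  C6    U A   4      -0.024   5.053   0.000  1.00  0.00           C
TER
END
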