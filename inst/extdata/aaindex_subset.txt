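H BLAS910101
D Scaled side chain hydrophobicity values (Black-Mould, 1991)
R LIT:1616690 PMID:2006754
A Black, S.D. and Mould, D.R.
T Development of hydrophobicity parameters to analyze proteins which
  bear post- or cotranslational modifications
J Anal. Biochem. 193, 72-82 (1991)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.616   0.000   0.236   0.028   0.680   0.251   0.043   0.501   0.165   0.943
    0.943   0.283   0.738   1.000   0.711   0.359   0.450   0.878   0.880   0.825
//
H PUNT030101
D Knowledge-based membrane-propensity scale from 1D_Helix in MPtopo databases
R LIT:2004063b PMID:12547207
A Punta, M. and Maritan, A.
T A knowledge-based scale for amino acid membrane propensity
J Proteins 50, 114-121 (2003)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   -0.17    0.37    0.18    0.37   -0.06    0.26    0.15    0.01   -0.02   -0.28
   -0.28    0.32   -0.26   -0.41    0.13    0.05    0.02   -0.15   -0.09   -0.17
//
H WOLR810101
D Hydration potential (Wolfenden et al., 1981)
R LIT:0706055 PMID:7284370
A Wolfenden, R., Andersson, L., Cullis, P.M. and Southgate, C.C.B.
T Affinities of amino acid side chains for solvent water
J Biochemistry 20, 849-855 (1981)
* The original index has no value for Pro; the value below (-3.68) is the
* imputation used in the curated 531-property rearrangement of AAindex.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.94  -19.92   -9.68  -10.95   -1.24   -9.38  -10.20    2.39  -10.27    2.15
    2.28   -9.52   -1.48   -0.76   -3.68   -5.06   -4.88   -5.88   -6.11    1.99
//
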