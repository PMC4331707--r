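# Published photosynthetic-protein (PSP) reference values: the 20 amino-acid
# propensity scores of the optimised PSP scoring card, with the pooled
# amino-acid compositions (%) of the PSP and non-PSP training classes
# (133,744 and 210,361 residues respectively) and their difference.
# Note: the printed Cys compositions are equal (1.06/1.06) yet the printed
# difference is -0.69; the difference column is kept verbatim because the
# published footer correlation (R = 0.96) is computed from it.
aa	propensity	rank	comp_pos_pct	comp_neg_pct	comp_diff_pct
A	522.90	1	9.97	8.03	1.94
F	516.70	2	5.12	3.68	1.43
Y	498.90	3	3.34	2.68	0.66
I	495.80	4	6.36	5.41	0.95
L	484.90	5	11.28	10.20	1.08
G	482.70	6	7.70	6.95	0.75
V	448.60	7	7.45	6.73	0.72
M	447.70	8	2.77	2.26	0.51
P	429.30	9	4.72	5.09	-0.36
W	417.40	10	1.29	1.14	0.15
T	413.60	11	5.07	5.21	-0.14
S	383.60	12	6.79	7.40	-0.61
N	376.10	13	3.40	3.85	-0.45
H	373.30	14	1.75	2.33	-0.58
C	371.10	15	1.06	1.06	-0.69
K	370.70	16	4.58	5.51	-0.93
D	358.80	17	4.35	5.24	-0.89
R	356.70	18	4.80	5.78	-0.98
E	350.90	19	5.33	6.64	-1.31
Q	313.10	20	2.90	4.12	-1.23
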