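# Hydroxyl-radical side-chain reaction rate constants (M^-1 s^-1) for the 20
# amino acids, alongside the PSP propensity column exactly as printed in the
# published rate-constant analysis. CAUTION: that propensity column disagrees
# with the reference card for T, S, N, H and C (apparent transcription
# errors), and the published correlations computed from it (0.31 overall,
# 0.50 after excluding A, P, G) could not be reproduced from the printed
# data under linear or log conventions; the columns are distributed verbatim
# for documentation and for the generic external-scale correlation API, not
# as validation targets.
aa	propensity_printed	rate_constant
A	522.9	7.7e7
F	516.7	6.5e9
Y	498.9	1.3e10
I	495.8	1.8e9
L	484.9	1.7e9
G	482.7	1.7e7
V	448.6	7.6e8
M	447.7	8.3e9
P	429.3	4.8e8
W	417.4	1.3e10
T	482.7	5.1e8
S	448.6	3.2e8
N	447.7	4.9e7
H	429.3	1.3e10
C	417.4	3.4e10
K	370.7	3.4e8
D	358.8	7.5e7
R	356.7	3.5e9
E	350.9	2.3e8
Q	313.1	5.4e8
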