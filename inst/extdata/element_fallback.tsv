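element	radius	volume
C	1.821	17.93
N	1.65	16.62
O	1.4	16.03
S	1.85	32.95
P	1.9	25
FE	1.47	12
CA	1.74	12
ZN	1.39	12
MG	1.73	12
X	1.8	20
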