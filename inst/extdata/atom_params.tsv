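element	sigma_A	epsilon_kcal	radius_A
H	2.47	0.0157	1.20
C	3.40	0.0860	1.70
N	3.25	0.1700	1.55
O	2.96	0.2100	1.52
S	3.56	0.2500	1.80
P	3.74	0.2000	1.80
F	3.12	0.0610	1.47
CL	3.47	0.2650	1.75
BR	3.60	0.3200	1.85
NA	2.43	0.0874	2.27
MG	2.11	0.0880	1.73
ZN	1.96	0.0125	1.39
FE	2.59	0.0130	1.52
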