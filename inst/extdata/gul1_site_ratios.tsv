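site	peptide_key	ratio_pro11	ratio_pp2Ac1pro22	ratio_pro11pro22
S180	S180_pep1	1.34	1.53	1.35
S180	S180_pep2	1.35	1.39	1.37
S180	S180_pep3	1.20	1.95	1.50
S210	S210_pep1	0.96	0.10	0.49
S216	S216_pep1	0.69	0.51	0.63
S510	S510_pep1	1.73	1.40	2.04
S510	S510_pep2	1.49	1.17	1.26
S1198	S1198_pep1	0.38	0.50	0.74
T1287	T1287_pep1	0.86	0.37	1.65
S1289	S1289_pep1	1.08	0.78	1.30
S1289	S1289_pep2	1.05	0.77	1.00
S1291	S1291_pep1	0.43	0.35	0.63
S1291	S1291_pep2	0.43	0.02	0.24
T1298	T1298_pep1	1.02	1.10	1.02
T1298	T1298_pep2	0.76	0.31	0.54
S1343	S1343_pep1	0.79	0.54	0.59
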