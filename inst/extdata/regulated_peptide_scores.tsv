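protein_id	peptide	site	score_pro11	score_pp2Ac1pro22	score_pro11pro22
SMAC_02471	HEVPRsPDEAK	S506	2.55	2.34	2.63
SMAC_02471	GESIAsPISSR	S1200	2.85	2.58	3.30
SMAC_04490	RVPsEHEGPk	S422	2.61	2.49	2.12
SMAC_03824	SHsEDQPREPIK	S607	2.87	2.70	2.68
SMAC_03824	REsIQMR	S677	2.53	2.84	2.47
SMAC_03824	GETSGGsNERLEPEDPDLAKPVFLK	S733	2.48	2.03	2.75
SMAC_03681	SAsASGLGR	S889	3.11	2.90	2.16
SMAC_05230	QDGTRPQtPLK	T22	2.42	3.72	2.89
SMAC_06647	GRsIEPPSSR	S83	2.37	2.88	2.47
SMAC_06647	DGHLsPDRR	S117	3.94	3.85	2.51
SMAC_07806	SQASLDDSSsVTkR	S902	2.32	2.94	2.46
SMAC_07806	SQAsLDDSSSVTkR	S896	3.53	3.48	3.19
SMAC_08582	TPEPsKLPDHRQSPR	S53	3.31	2.60	3.19
SMAC_08582	LPDHRQsPR	S53	2.82	3.58	3.93
SMAC_08582	LERtPEPSk	T41	3.52	3.22	2.95
SMAC_08582	DLDRPPsR	S125	3.11	3.42	3.63
SMAC_00192	SEPQAPVESSSsRPTTSAK	S732	4.35	4.18	5.02
SMAC_00192	RPPSSQQNAGNTPTAGNAVAPPRPsRDGR	S788	2.45	2.51	2.77
SMAC_04153	RLsPQGRPR	S240	4.68	4.45	4.98
SMAC_04153	LDRVsHEPVPTTAK	S451	2.63	2.24	2.72
SMAC_04153	GTQsARAsVDRDTR	T643, S649	2.63	3.36	2.65
SMAC_04153	GTQSARAsVDRDTR	S649	3.65	3.34	4.30
SMAC_04153	GTQsARAsVDRDTR	S645, S649	2.32	2.69	2.05
SMAC_04153	GTQsARAsVDRDTR	S645	3.82	4.48	4.32
SMAC_04153	DRSPPPPyRDR	Y104	2.35	2.88	3.23
SMAC_04153	DRsPPPPYR	S99	2.47	2.39	2.46
SMAC_12586	SsVGDASQAVGSR	S259	2.34	2.69	2.54
SMAC_01781	KTGAAQGGGsGAASPQP	S689	2.60	2.22	2.16
SMAC_03223	SYDVDkHPsPR	S143	2.68	2.03	3.00
SMAC_03223	LPPGQLPLSAYPVsPR	S247	2.15	2.45	2.65
SMAC_06177	YPsPQKEGYR	S155	2.73	2.43	3.51
SMAC_06177	TERtPIERPER	T111	3.29	2.64	3.81
SMAC_06177	AEQYEPSRPQsNSHER	S147	3.63	2.94	4.05
SMAC_07544	SGsISGGQNTGDDNGNAEGGLRR	S510	2.79	2.09	3.58
SMAC_07544	RHsLALADAKK	S180	2.16	2.28	2.37
SMAC_07544	RHsLALADAK	S180	2.18	2.07	2.40
SMAC_00366	SRsPLPR	S238	3.65	3.15	3.89
SMAC_00366	sFRDDAPR	S56	2.56	3.30	2.89
SMAC_00366	QsPELSSDPR	S88	2.94	2.75	2.56
SMAC_00366	KsFRDDAPR	S56	2.23	2.00	2.07
SMAC_00366	ITVPGGRsR	S202	3.03	2.42	3.70
SMAC_00366	GRsRsPLPR	S236, S238	2.45	2.21	2.46
SMAC_01892	RGPLPPQEPTEQIRDSsR	S258	2.06	2.12	3.91
SMAC_01892	GPLPPQEPTEQIRDSsR	S258	2.60	2.22	2.26
SMAC_01892	gPLPPQEPTEQIRDsSR	S257	3.08	2.78	2.88
SMAC_01892	GEsFRNDR	S269	3.06	2.84	2.37
SMAC_01892	DGETFDGRsIR	S171	2.71	2.63	2.91
SMAC_03445	EEELRRsYEAAR	S330	3.74	2.46	3.72
SMAC_03877	GGYRsPPRRPLDDYPPPR	S247	2.34	2.01	2.75
SMAC_03877	GGYRsPPR	S247	4.73	3.85	4.07
SMAC_03877	EGGPGFTHERNsQPRPR	S95	3.37	3.01	3.32
SMAC_03877	DGYRDRsPPPR	S230	2.63	2.15	2.35
SMAC_04425	tPTPGKYFGPPK	T157	2.10	2.10	2.04
SMAC_04425	tPTPGK	T157	3.03	2.84	2.05
SMAC_04425	DAAPGTSsYGEPAPR	S235	2.03	2.15	2.07
SMAC_04425	ARPRTPtPGK	T157	2.56	4.12	2.89
SMAC_04785	KEEGAEGSTsPATEALK	S186	2.47	2.07	2.58
SMAC_08082	LTAFsPDDNSAR	S38	4.85	2.78	4.28
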