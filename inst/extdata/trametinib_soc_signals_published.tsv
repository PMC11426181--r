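# Published SOC-level signal table for trametinib in FAERS (2013Q2-2023Q4):
# case reports and the four disproportionality statistics as printed
# (point estimates to 2 decimals; interval bounds in parentheses in the
# original are given as *_lo / *_hi columns; ic025/ebgm05 are lower bounds).
soc	n	ror	ror_lo	ror_hi	prr	prr_lo	prr_hi	chi2	ic	ic025	ebgm	ebgm05
General disorders and administration site conditions	1254	0.83	0.78	0.88	0.85	0.8	0.9	38.56	-0.23	-0.31	0.85	0.81
Neoplasms benign, malignant, and unspecified (incl cysts and polyps)	802	3.59	3.33	3.86	3.32	3.13	3.52	1342.08	1.73	1.63	3.32	3.12
Investigations	794	1.74	1.61	1.87	1.66	1.57	1.76	223.17	0.73	0.63	1.66	1.56
Gastrointestinal disorders	790	1.16	1.08	1.25	1.15	1.08	1.22	16.02	0.2	0.09	1.15	1.08
Infections and infestations	673	1.58	1.46	1.71	1.53	1.41	1.65	131.18	0.61	0.5	1.53	1.43
Skin and subcutaneous tissue disorders	549	1.22	1.12	1.33	1.21	1.12	1.31	20.46	0.27	0.15	1.21	1.12
Nervous system disorders	397	0.58	0.52	0.64	0.6	0.54	0.66	116.61	-0.74	-0.89	0.6	0.55
Respiratory, thoracic, and mediastinal disorders	390	1.02	0.92	1.13	1.02	0.92	1.13	0.14	0.03	-0.12	1.02	0.94
Injury, poisoning, and procedural complications	375	0.42	0.38	0.46	0.45	0.41	0.5	287.82	-1.16	-1.31	0.45	0.41
Eye disorders	298	1.88	1.67	2.11	1.84	1.64	2.07	117.67	0.88	0.72	1.84	1.67
Blood and lymphatic system disorders	279	2.12	1.88	2.39	2.08	1.85	2.34	158.61	1.05	0.88	2.08	1.88
Metabolism and nutrition disorders	273	1.63	1.44	1.84	1.61	1.43	1.81	64.22	0.69	0.51	1.61	1.45
Cardiac disorders	232	1.24	1.09	1.41	1.23	1.09	1.38	10.49	0.3	0.11	1.23	1.11
Musculoskeletal and connective tissue disorders	184	0.41	0.35	0.47	0.42	0.37	0.48	153.87	-1.24	-1.45	0.42	0.37
Hepatobiliary disorders	137	2.05	1.73	2.42	2.03	1.74	2.37	72.07	1.02	0.78	2.03	1.76
Vascular disorders	132	0.79	0.66	0.94	0.79	0.66	0.94	7.44	-0.34	-0.59	0.79	0.68
Renal and urinary disorders	130	0.82	0.69	0.98	0.83	0.7	0.99	4.86	-0.28	-0.52	0.83	0.71
Psychiatric disorders	73	0.15	0.12	0.19	0.16	0.13	0.2	333.76	-2.62	-2.95	0.16	0.13
Endocrine disorders	30	1.44	1.01	2.07	1.44	1.01	2.05	4.06	0.53	0.02	1.44	1.07
Immune system disorders	25	0.26	0.17	0.38	0.26	0.18	0.38	53.38	-1.94	-2.5	0.26	0.19
Congenital, familial, and genetic disorders	18	0.75	0.47	1.2	0.75	0.47	1.2	1.45	-0.41	-1.06	0.75	0.51
Reproductive system and breast disorders	14	0.22	0.13	0.36	0.22	0.13	0.37	39.95	-2.21	-2.94	0.22	0.14
Ear and labyrinth disorders	13	0.36	0.21	0.63	0.36	0.21	0.62	14.46	-1.46	-2.21	0.36	0.23
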