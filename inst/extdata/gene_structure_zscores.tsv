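gene	FL	Ins	CgG	HP	PHG	OL	PL	TL	Amy	BF	GP	Str	Cla	ET	HT	ST	DT	VT
MART	1.5	1.5	1.3	0.29	0.14	1.2	1.4	1.5	–0.48	0.18	–0.67	–1.3	0.11	–2.2	–0.36	–0.45	–0.09	–0.85
APOE	–0.87	–0.63	–0.57	–1.2	–0.03	–0.48	–0.79	–0.58	1	1.4	2.4	1.2	–0.48	0.34	0.71	0.38	1	0.8
PICALM	–1	–1.3	–0.94	–0.39	–0.76	–0.75	–0.9	–1	0.04	0.74	0.97	–0.33	0.4	–0.75	–0.61	0	–0.06	2
BIN1	–0.55	–0.6	–0.39	0.53	–0.67	–0.42	–0.51	–0.47	–0.06	0.65	0.88	–0.55	0.2	–2.1	–1.3	0.45	0.32	1.4
CLU	0.61	0.76	0.73	0.76	0.48	0.51	0.55	0.73	0.55	0.86	0.25	2.4	0.13	–1.2	–0.13	–0.29	0.02	–0.57
CR1	–0.24	–0.25	–0.12	–1.1	0.19	–0.68	–0.04	0.39	–0.25	–1.1	–0.62	–0.38	–0.43	–0.87	–0.96	0.4	–0.55	1.4
ABCA7	–0.7	–1	–0.55	1	–1.6	–0.24	–0.8	–0.94	0.93	1.6	–1.5	–1.8	0.84	–0.49	–0.48	1.4	0.11	0.73
SORL1	0.31	–0.38	–0.07	0.31	–0.6	0.93	0.56	–0.08	–1.6	–1.1	0.79	–2.4	–0.12	0.73	–0.95	0.8	–0.31	0.85
PLEKHC1	–0.97	–0.84	–0.47	–0.85	0.04	–0.94	–0.83	–0.79	1.6	1.1	1.8	0.26	0.79	–0.19	0.15	0.48	0.34	1.2
CD2AP	–1	–1.5	–1.3	–0.59	–0.67	–0.01	–0.59	–0.83	0.08	–1.3	0.62	0.4	–1.1	1.1	0.17	–0.12	0.52	–0.1
CD33	–0.86	–0.85	–1.2	–0.76	–0.31	–1.4	–0.95	–0.65	0.54	–0.41	0.86	–0.79	0.57	0.36	–0.49	1.2	–0.32	1.3
APP	–0.29	–0.43	–0.12	0.42	0.16	0.09	–0.05	–0.2	0.7	0.01	0.47	–0.36	2	–1.1	–1.1	–0.29	0.11	1.3
PSEN1	–0.56	–0.82	–0.56	–1.1	–0.98	–0.75	–0.68	–0.66	–1	0.66	1.1	–0.34	–0.59	–0.61	–1.1	0.41	–0	1.3
PSEN2	–0.86	–0.79	–0.77	–0.43	–0.75	–1.3	–0.98	–0.85	–0.23	0.8	–0.5	–0.68	1.8	–0.93	0.59	1.5	0.83	0.77
CASS	–0.36	–0.28	–1.1	–0.88	–0.37	–0.64	–0.75	0.41	0.14	1.2	1.8	0.97	–0.77	–1.7	0.89	–0.51	0.83	0.77
EPHA1	–0.21	–0.31	–0.29	–0.48	0.05	–0.53	0.29	0.03	–0.05	–0.6	–0.9	–0.49	0.4	–0.72	–0.86	0.07	–0.32	0.78
PTK2B	0.58	0.35	0.36	2.2	–0.21	0.4	0.54	0.34	1.6	0.54	–1.6	–0.51	0.73	–1.8	–1.5	–0.75	0.89	0.73
INPP5D	–0.89	–0.82	–1.1	–1.2	–1.1	0.43	–0.68	–0.77	–0.43	0.21	1.5	0.43	–0.49	1.7	0.04	1.1	–0.12	0.47
MEF2C	1.3	1.4	1.3	–0.21	1.1	1.4	1.4	1.4	0.64	–0.35	–0.73	–0.66	1.5	–0.81	–0.8	–0.73	–0.74	–0.4
CUGBP1	0.34	0.18	0.48	1.7	0.76	0.93	0.61	0.42	1.6	0.84	–0.64	0.55	1.8	–0.52	–0.48	–1.1	0.82	–0.46
MAAD	–0.37	–0.41	0.27	1.6			0.04	–0.15	2.3	0.48	–0.98	0.3	2.1	–0.96	–0.59	–0.01	–0.72	1.3
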