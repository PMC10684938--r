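entry	q_sativa	q_longistaminata	q_barthii_glaberrima	origin	type
Bt136	0.46	0.54	0.00	F2 control	control
Bt135	0.47	0.53	0.00	F1 control	control
Bt137	0.49	0.51	0.00	F2 control	control
RILs15	0.82	0.18	0.00	RIL	control
RILs47	0.84	0.16	0.00	RIL	control
RILs31	0.86	0.14	0.00	RIL	control
RILs24	0.86	0.14	0.00	RIL	control
RILs60	0.88	0.12	0.00	RIL	control
RILs3	0.88	0.12	0.00	RIL	control
RILs43	0.88	0.12	0.00	RIL	control
RILs23	0.89	0.11	0.00	RIL	control
RILs27	0.89	0.11	0.00	RIL	control
RILs78	0.89	0.11	0.00	RIL	control
RILs11	0.89	0.11	0.00	RIL	control
RILs48	0.90	0.10	0.00	RIL	control
RILs42	0.90	0.10	0.00	RIL	control
RILs59	0.95	0.05	0.00	RIL	control
101741.002	0.79	0.18	0.04	Senegal	putative
101211.001	0.71	0.29	0.00	Cote D'Ivoire	putative
104300.002	0.46	0.53	0.02	Malawi	putative
105075.002	0.44	0.55	0.01	Nigeria	putative
101222.002	0.42	0.58	0.00	Mali	putative
110404.002	0.42	0.56	0.02	India (Mali)	putative
92650.002	0.39	0.61	0.01	Mali	putative
89159.002	0.37	0.62	0.01	Mozambique	putative
103886.001	0.34	0.66	0.00	Tanzania	putative
106456.002	0.32	0.67	0.01	Mali	putative
101211.002	0.32	0.68	0.00	Cote D'Ivoire	putative
101222.001	0.24	0.76	0.00	Mali	putative
89155.001	0.24	0.75	0.01	Mozambique	putative
86480.002	0.20	0.80	0.00	Zambia	putative
104300.001	0.19	0.81	0.00	Malawi	putative
103886.002	0.19	0.81	0.00	Tanzania	putative
86480.001	0.15	0.85	0.00	Zambia	putative
105183.002	0.08	0.92	0.00	Ghana	putative
101431.001	0.05	0.95	0.00	Tanzania	putative
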