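trait	A	D	AA	AD	DA	DD	AE	DE	AAE	ADE	T
Protein	12.51	15.74	1.72	21.18	10.85	31.43	NA	NA	NA	NA	93.43
Oil	10.14	33.44	10.79	6.98	14.35	6.21	NA	3.69	NA	7.76	93.36
Palmitic	18.30	24.90	2.17	NA	3.72	36.79	NA	NA	NA	NA	85.88
Linoleic	14.15	45.09	0.79	3.89	NA	20.00	1.28	1.24	NA	NA	86.44
Oleic	23.13	54.99	2.69	NA	NA	NA	0.92	NA	NA	NA	81.73
Myristic	34.01	36.84	NA	NA	NA	NA	1.07	NA	2.24	NA	74.16
Stearic	19.79	23.37	NA	NA	NA	NA	25.05	3.41	NA	NA	71.62
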