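species	stratum	avg_abundance_pct	sd_abundance_pct	prevalence_pct	correlations_total	correlations_positive	correlations_negative
Bifidobacterium adolescentis	all	1.04	2.81	54.03	340	226	114
Bifidobacterium adolescentis	Africa	0.22	0.77	33.33	31	24	7
Bifidobacterium adolescentis	Asia	0.77	2.55	36.89	111	79	32
Bifidobacterium adolescentis	Europe	1.39	2.90	69.82	204	122	82
Bifidobacterium adolescentis	North America	0.52	1.36	55.74	47	41	6
Bifidobacterium adolescentis	Oceania	0.95	2.48	63.64	8	8	0
Bifidobacterium adolescentis	South America	2.97	6.11	76.65	32	28	4
Bifidobacterium bifidum	all	0.19	0.85	19.60	202	138	64
Bifidobacterium breve	all	0.03	0.45	7.11	280	116	164
Bifidobacterium catenulatum	all	0.07	0.43	17.90	263	172	91
Bifidobacterium dentium	all	0.02	0.26	8.31	302	235	67
Bifidobacterium longum	all	0.86	2.86	71.21	416	272	144
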