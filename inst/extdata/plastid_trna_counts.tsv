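amino_acid	anticodon	locus_id	organelle	mature_wt	leader_wt	log2_wt	mature_rnai	leader_rnai	log2_rnai	p_value	adj_p
His	GTG	ATCG00010	plastid	587,933	38	13.92	1,039,481	119	13.10	9.37E-004	2.81E-002
Gln	TTG	ATCG00060	plastid	10,784	47	7.84	29,908	71	8.72	9.99E-001	1.00E+000
Ser	GCT	ATCG00090	plastid	18,967	140	7.08	51,117	170	8.23	1.00E+000	1.00E+000
Arg	TCT	ATCG00110	plastid	17,656	60	8.20	25,274	81	8.29	6.68E-001	1.00E+000
Cys	GCA	ATCG00200	plastid	402	12	5.07	888	95	3.22	2.45E-006	8.10E-005
Asp	GTC	ATCG00230	plastid	423,255	294	10.49	442,408	351	10.30	5.01E-002	1.00E+000
Tyr	GTA	ATCG00240	plastid	18,228	135	7.08	11,151	230	5.60	6.05E-022	2.12E-020
Glu	TTC	ATCG00250	plastid	73,516	263	8.13	98,975	375	8.04	2.51E-001	1.00E+000
Thr	GGT	ATCG00260	plastid	667	232	1.52	1,529	283	2.43	1.00E+000	1.00E+000
Ser	TGA	ATCG00290	plastid	136	46	1.56	353	106	1.74	7.56E-001	1.00E+000
Gly	GCC	ATCG00310	plastid	106,563	221	8.91	207,724	552	8.56	9.06E-004	2.81E-002
Met_i	CAT	ATCG00320	plastid	165,918	1,529	6.76	328,644	2,355	7.12	1.00E+000	1.00E+000
Ser	GGA	ATCG00370	plastid	15,326	30	9.00	72,110	49	10.52	9.99E-001	1.00E+000
Thr	TGT	ATCG00390	plastid	111	72	0.62	348	149	1.22	9.91E-001	1.00E+000
Phe	GAA	ATCG00410	plastid	953	177	2.43	516	536	-0.05	3.71E-071	1.82E-069
Met_e	CAT	ATCG00460	plastid	159	37	2.10	406	55	2.88	9.92E-001	1.00E+000
Trp	CCA	ATCG00610	plastid	9,553	94	6.67	20,220	108	7.55	9.99E-001	1.00E+000
Pro	TGG	ATCG00620	plastid	3,078	55	5.81	9,963	81	6.94	9.99E-001	1.00E+000
Arg	ACG	ATCG00980	plastid	4,002	387	3.37	1,000	386	1.37	1.01E-064	3.64E-063
Val	GAC	ATCG00910	plastid	945	27	5.13	387	70	2.47	4.29E-017	1.46E-015
Leu	TAG	ATCG01030	plastid	6,076	11	9.11	6941	20	8.44	1.43E-001	1.00E+000
Asn	GTT	ATCG01140	plastid	7,039	403	4.13	14,784	867	4.09	3.62E-001	1.00E+000
Ala	TGC	ATCG01190	plastid	4,763	533	3.16	6,808	309	4.46	1.00E+000	1.00E+000
Leu	CAA	ATCG01260	plastid	51,895	119	8.77	97,720	262	8.54	8.61E-002	1.00E+000
Ile	CAT	ATCG01290	plastid	97	11	3.14	140	35	2.00	2.04E-002	5.70E-001
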