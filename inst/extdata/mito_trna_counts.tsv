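amino_acid	anticodon	locus_id	organelle	mature_wt	leader_wt	log2_wt	mature_rnai	leader_rnai	log2_rnai	p_value	adj_p
Lys	TTT	ATMG00100	mitochondrion	493	-	-	475	6	6.31	-	-
Gly	GCC	ATMG00190	mitochondrion	169	7	4.59	149	3	5.63	9.18E-001	1.00E+000
Ser	GGA	ATMG00230	mitochondrion	15	-	-	69	-	-	-	-
Met_i	CAT	ATMG00250	mitochondrion	18	27	-0.58	20	22	-0.14	8.24E-001	1.00E+000
Ser	GCT	ATMG00330	mitochondrion	118	1061	-3.17	139	347	-1.32	1.00E+000	1.00E+000
Tyr	GTA	ATMG00340	mitochondrion	733	85	3.11	292	39	2.90	2.77E-001	1.00E+000
Pro	TGG	ATMG00350	mitochondrion	5,618	-	-	5880	1	12.52	-	-
Cys	GCA	ATMG00360	mitochondrion	39,297	19	11.01	13,876	-	-	-	-
Asn	GTT	ATMG00380	mitochondrion	341	2	7.41	652	4	7.35	6.61E-001	1.00E+000
Tyr	GTA	ATMG00390	mitochondrion	154	1	7.27	151	3	5.65	3.09E-001	1.00E+000
Ser	TGA	ATMG00420	mitochondrion	24	122	-2.35	47	138	-1.55	9.83E-001	1.00E+000
Ile	CAT	ATMG00460	mitochondrion	9	3	1.58	10	3	1.74	7.19E-001	1.00E+000
Tyr	GTA	trnY-GTA_nc	mitochondrion	799	19	5.39	311	27	3.53	2.06E-005	6.58E-004
Ser	GCT	ATMG00780	mitochondrion	83	-	-	124	-	-	-	-
Glu	TTC	ATMG00800	mitochondrion	267	248	0.11	202	93	1.12	1.00E+000	1.00E+000
Trp	CCA	ATMG00930	mitochondrion	1,964	1	10.94	4878	-	-	-	-
Gln	TTG	ATMG00950	mitochondrion	45	-	-	83	-	-	-	-
Asp	GTC	ATMG01070	mitochondrion	11,777	7	10.72	6608	12	9.11	1.45E-002	4.20E-001
Met_e	CAT	ATMG01340	mitochondrion	2	4	-1	-	1	-	-	-
His	GTG	trnH-GTG_nc	mitochondrion	8,969	-	-	5698	-	-	-	-
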