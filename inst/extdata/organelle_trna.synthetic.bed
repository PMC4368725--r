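pt	1000	1070	ATCG00010	0	+	plastid	0	.	.	His	GTG
pt	5000	5074	ATCG00060	0	+	plastid	0	.	.	Gln	TTG
pt	9000	9070	ATCG00090	0	-	plastid	0	.	.	Ser	GCT
pt	13000	13078	ATCG00110	0	+	plastid	0	.	.	Arg	TCT
pt	17000	17079	ATCG00200	0	+	plastid	0	.	.	Cys	GCA
pt	21000	21073	ATCG00230	0	-	plastid	0	.	.	Asp	GTC
pt	25000	25071	ATCG00240	0	+	plastid	0	.	.	Tyr	GTA
pt	29000	29079	ATCG00250	0	+	plastid	0	.	.	Glu	TTC
pt	33000	33070	ATCG00260	0	-	plastid	0	.	.	Thr	GGT
pt	37000	37077	ATCG00290	0	+	plastid	0	.	.	Ser	TGA
pt	41000	41076	ATCG00310	0	+	plastid	0	.	.	Gly	GCC
pt	45000	45073	ATCG00320	0	-	plastid	0	.	.	Met_i	CAT
pt	49000	49078	ATCG00370	0	+	plastid	0	.	.	Ser	GGA
pt	53000	53074	ATCG00390	0	+	plastid	0	.	.	Thr	TGT
pt	57000	57073	ATCG00410	0	-	plastid	0	.	.	Phe	GAA
pt	61000	61079	ATCG00460	0	+	plastid	0	.	.	Met_e	CAT
pt	65000	65071	ATCG00610	0	+	plastid	0	.	.	Trp	CCA
pt	69000	69072	ATCG00620	0	-	plastid	0	.	.	Pro	TGG
pt	73000	73078	ATCG00980	0	+	plastid	0	ir_acg_00980	inverted_repeat	Arg	ACG
pt	77000	77078	ATCG00910	0	+	plastid	0	ir_gac_00910	inverted_repeat	Val	GAC
pt	81000	81080	ATCG01030	0	-	plastid	0	.	.	Leu	TAG
pt	85000	85073	ATCG01140	0	+	plastid	0	ir_gtt_01140	inverted_repeat	Asn	GTT
pt	89000	89074	ATCG01190	0	+	plastid	0	.	.	Ala	TGC
pt	93000	93074	ATCG01260	0	+	plastid	0	ir_caa_01260	inverted_repeat	Leu	CAA
pt	97000	97073	ATCG01290	0	+	plastid	0	ir_cat_01290	inverted_repeat	Ile	CAT
pt	101000	101071	trnK-TTT	0	+	plastid	1	.	.	Lys	TTT
pt	105000	105077	trnG-TCC	0	-	plastid	1	.	.	Gly	TCC
pt	109000	109072	trnL-TAA	0	+	plastid	1	.	.	Leu	TAA
pt	113000	113079	trnV-TAC	0	+	plastid	1	.	.	Val	TAC
pt	117000	117070	trnI-GAT_1	0	-	plastid	1	.	.	Ile	GAT
pt	121000	121079	trnI-GAT_2	0	+	plastid	1	.	.	Ile	GAT
pt	125000	125077	trnA-TGC_1	0	+	plastid	1	.	.	Ala	TGC
pt	129000	129080	trnA-TGC_2	0	-	plastid	1	.	.	Ala	TGC
pt	133000	133075	ATCG00910_ir	0	-	plastid	0	ir_gac_00910	inverted_repeat	Val	GAC
pt	137000	137079	ATCG00980_ir	0	-	plastid	0	ir_acg_00980	inverted_repeat	Arg	ACG
pt	141000	141077	ATCG01140_ir	0	-	plastid	0	ir_gtt_01140	inverted_repeat	Asn	GTT
pt	145000	145073	ATCG01260_ir	0	-	plastid	0	ir_caa_01260	inverted_repeat	Leu	CAA
pt	149000	149073	ATCG01290_ir	0	-	plastid	0	ir_cat_01290	inverted_repeat	Ile	CAT
mt	5000	5075	ATMG00100	0	+	mitochondrion	0	td_atmg00100	tandem	Lys	TTT
mt	17000	17071	ATMG00190	0	+	mitochondrion	0	.	.	Gly	GCC
mt	29000	29074	ATMG00230	0	-	mitochondrion	0	.	.	Ser	GGA
mt	41000	41073	ATMG00250	0	+	mitochondrion	0	.	.	Met_i	CAT
mt	53000	53071	ATMG00330	0	+	mitochondrion	0	.	.	Ser	GCT
mt	65000	65077	ATMG00340	0	-	mitochondrion	0	td_atmg00340	tandem	Tyr	GTA
mt	77000	77071	ATMG00350	0	+	mitochondrion	0	.	.	Pro	TGG
mt	89000	89072	ATMG00360	0	+	mitochondrion	0	.	.	Cys	GCA
mt	101000	101077	ATMG00380	0	-	mitochondrion	0	.	.	Asn	GTT
mt	113000	113076	ATMG00390	0	+	mitochondrion	0	.	.	Tyr	GTA
mt	125000	125070	ATMG00420	0	+	mitochondrion	0	td_atmg00420	tandem	Ser	TGA
mt	137000	137074	ATMG00460	0	+	mitochondrion	0	.	.	Ile	CAT
mt	191953	192025	trnY-GTA_nc	0	+	mitochondrion	0	.	.	Tyr	GTA
mt	200000	200079	ATMG00700	0	+	mitochondrion	0	td_atmg00100	tandem	Lys	TTT
mt	212000	212071	ATMG00780	0	-	mitochondrion	0	.	.	Ser	GCT
mt	224000	224075	ATMG00790	0	-	mitochondrion	0	td_atmg00340	tandem	Tyr	GTA
mt	236000	236075	ATMG00800	0	+	mitochondrion	0	.	.	Glu	TTC
mt	248000	248071	ATMG00930	0	+	mitochondrion	0	.	.	Trp	CCA
mt	260000	260073	ATMG00950	0	-	mitochondrion	0	.	.	Gln	TTG
mt	272000	272072	ATMG01070	0	+	mitochondrion	0	.	.	Asp	GTC
mt	284000	284075	ATMG01160	0	+	mitochondrion	0	td_atmg00420	tandem	Ser	TGA
mt	296000	296074	ATMG01340	0	+	mitochondrion	0	.	.	Met_e	CAT
mt	359665	359739	trnH-GTG_nc	0	+	mitochondrion	0	.	.	His	GTG
1	10000	10075	trnF-GAA_nuc	0	+	nucleus	0	.	.	Phe	GAA
1	20000	20072	trnG-GCC_nuc	0	-	nucleus	0	.	.	Gly	GCC
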