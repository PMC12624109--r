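no	cpg_id	snp_id	chromosome	position	position_alt	position_flag	gene_symbol	beta_sign_tissue	meqtl_p_tissue	beta_sign_blood	meqtl_p_blood	tumor_meth_level	tumor_expr_level	r
1	cg19220282	rs66719815	chr2	65212470	NA	consistent	SLC1A4	+	6.36E-15	+	9.93E-201	Low	High	-0.42
2	cg09596674	rs939408	chr3	46599079	46607350	discordant_sources	LRRC2	-	1.75E-05	-	6.89E-08	High	Low	-0.32
3	cg10700718	rs12680375	chr8	1988076	NA	consistent	MYOM2	-	0.02	-	1.38E-06	Low	Low	0.35
4	cg04065210	rs328890	chr7	35013449	NA	consistent	DPY19L1	+	0.02	+	8.01E-39	Low	High	-0.48
5	cg04571833	rs750373	chr2	173833960	NA	consistent	RAPGEF4	+	1.99E-14	+	3.80E-20	Low	Low	0.30
6	cg16110827	rs3743281	chr15	48056958	NA	consistent	SEMA6D	-	2.24E-19	-	1.63E-213	Low	Low	0.49
7	cg03230154	rs2885221	chr19	22839387	NA	consistent	ZNF492	+	2.01E-06	+	5.06E-47	High	Low	-0.46
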