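rsid	chrom	pos	effect_allele	other_allele	eaf	beta	se	pvalue	trait	scale
rs2153960	1	1000	A	G	0.14999999999999999	0.019541001560175079	0.018333603904643527	0.28648825247030624	AD	log_odds
rs1000002	1	2000	C	T	0.19444444444444445	0.0073913661917485475	0.016540834580470207	0.65497925244300981	AD	log_odds
rs1000003	1	3000	G	A	0.23888888888888887	-0.0064517967936631821	0.015352564489949497	0.67430846680886836	AD	log_odds
rs1000004	1	4000	T	C	0.28333333333333333	3.9016146605315412e-05	0.014527654356652552	0.99785716655890511	AD	log_odds
rs1000005	1	5000	A	C	0.32777777777777778	-0.0025441072581907235	0.01394622767085074	0.85525108290220386	AD	log_odds
rs1000006	1	6000	G	T	0.37222222222222223	0.0079704734496606269	0.013542499200821486	0.55616142221481191	AD	log_odds
rs1000007	1	7000	A	G	0.41666666666666663	0.012824710569901759	0.01327853493419268	0.33413290355415387	AD	log_odds
rs1000008	1	8000	T	C	0.53888888888888886	0.0099941854366597891	0.013132594312608343	0.44664427955097064	AD	log_odds
rs1000009	1	9000	A	G	0.49444444444444446	-0.021070590854740317	0.013093620285339782	0.1075669889816448	AD	log_odds
rs646776	1	10000	C	T	0.44999999999999996	-0.00029446042956483658	0.01315877118036774	0.9821468265908786	AD	log_odds
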