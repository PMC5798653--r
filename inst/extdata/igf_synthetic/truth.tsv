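rsid	eaf	b	se_x	se_y	theta	pleiotropy	raising_allele
rs2153960	0.14999999999999999	0.1596564940064493	0.011268422909109089	0.018333603904643527	0	0	A
rs1000002	0.19444444444444445	0.14404432815250451	0.010166529193703467	0.016540834580470207	0	0	C
rs1000003	0.23888888888888887	0.13369638796725747	0.0094361801592268719	0.015352564489949497	0	0	G
rs1000004	0.28333333333333333	0.12651273436387483	0.0089291638468669676	0.014527654356652552	0	0	T
rs1000005	0.32777777777777778	0.12144943384425384	0.0085718002962888347	0.01394622767085074	0	0	A
rs1000006	0.37222222222222223	0.11793360180213512	0.0083236557872005297	0.013542499200821486	0	0	G
rs1000007	0.41666666666666663	0.11563489339913179	0.0081614148549355517	0.01327853493419268	0	0	A
rs1000008	0.46111111111111114	0.11436398299349268	0.0080717150527480491	0.013132594312608343	0	0	C
rs1000009	0.50555555555555554	0.11402458128156664	0.0080477603614599897	0.013093620285339782	0	0	G
rs646776	0.55000000000000004	0.11459194182538811	0.0080878041980073714	0.01315877118036774	0	0	T
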