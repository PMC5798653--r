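rsid	chrom	pos	effect_allele	other_allele	eaf	beta	se	pvalue	trait	scale
rs2153960	1	1000	G	A	0.84999999999999998	-0.17659731024121847	0.011268422909109089	2.3552907585045041e-55	IGF1	sd_units
rs1000002	1	2000	T	C	0.80555555555555558	-0.14013498850334632	0.010166529193703467	3.1833962676587134e-43	IGF1	sd_units
rs1000003	1	3000	A	G	0.76111111111111107	-0.13263395224491178	0.0094361801592268719	7.0880671146696291e-45	IGF1	sd_units
rs1000004	1	4000	C	T	0.71666666666666667	-0.13027251810751128	0.0089291638468669676	3.2733053537923053e-48	IGF1	sd_units
rs1000005	1	5000	C	A	0.67222222222222228	-0.11572312405471817	0.0085718002962888347	1.5543306909637109e-41	IGF1	sd_units
rs1000006	1	6000	G	T	0.37222222222222223	0.12128806746142071	0.0083236557872005297	4.2648612387762052e-48	IGFBP3	sd_units
rs1000007	1	7000	A	G	0.41666666666666663	0.11861011401012196	0.0081614148549355517	7.4831985158624969e-48	IGFBP3	sd_units
rs1000008	1	8000	C	T	0.46111111111111114	0.11926950149669056	0.0080717150527480491	2.0852185410072543e-49	IGF1	sd_units
rs1000009	1	9000	G	A	0.50555555555555554	0.1136152919078019	0.0080477603614599897	2.9577796309851463e-45	IGF1	sd_units
rs646776	1	10000	T	C	0.55000000000000004	0.11142782936257541	0.0080878041980073714	3.4925028561004088e-43	IGF1	sd_units
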