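rsid	exposure_trait	raising_allele	affects
rs2153960	IGF1	A	igf1_only
rs1000002	IGF1	C	igf1_only
rs1000003	IGF1	G	igf1_only
rs1000004	IGF1	T	igf1_only
rs1000005	IGF1	A	igf1_only
rs1000006	IGFBP3	G	igfbp3_only
rs1000007	IGFBP3	A	igfbp3_only
rs1000008	IGF1	C	both
rs1000009	IGF1	G	both
rs646776	IGF1	T	bivariate_opposite
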