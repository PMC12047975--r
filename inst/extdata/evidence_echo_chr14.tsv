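symbol	description	coding_variant	gwas_hf	gwas_cvd	cis_regulated	deg	functional_relevance	expression_tpm	mr_significant	printed_total
Mycbp2	MYC binding protein 2, E3 ubiquitin protein ligase	--	--	Y	--	--	Y	2.79	--	4
Abcc4	ATP-binding cassette, sub-family C (CFTR/MRP), member 4	Nonsynonymous SNP	--	Y	--	Y	--	3.39	--	4
Slain1	SLAIN motif family, member 1	Nonsynonymous SNP	--	--	--	--	--	0.14	Y	3
Ednrb	endothelin receptor type B	Nonsynonymous SNP	--	--	--	Y	--	3.75	--	3
Gpc6	glypican 6	--	--	--	--	--	--	3.10	Y	3
Tgds	TDP-glucose 4,6-dehydratase	--	--	--	--	--	Y	2.29	--	3
Gpr180	G protein-coupled receptor 180	--	--	--	Y	Y	--	4.95	--	3
Uggt2	UDP-glucose glycoprotein glucosyltransferase 2	Nonsynonymous SNP	--	--	--	--	--	1.40	Y	3
Mbnl2	muscleblind like splicing factor 2	--	--	--	--	--	--	5.18	Y	3
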