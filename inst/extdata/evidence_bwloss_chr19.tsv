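symbol	description	coding_variant	gwas_hf	gwas_cvd	cis_regulated	deg	functional_relevance	expression_tpm	mr_significant	printed_total
Hspa12a	heat shock protein 12A	Nonsynonymous SNP	Y	Y	Y	--	--	3.35	Y	7
Rbm20	RNA binding motif protein 20	Nonsynonymous SNP	--	Y	--	Y	Y	6.92	--	6
Adrb1	adrenergic receptor, beta 1	--	--	Y	--	Y	Y	4.32	--	5
Pdzd8	PDZ domain containing 8	--	--	Y	--	Y	--	3.62	Y	5
Pdcd4	programmed cell death 4	--	--	--	--	Y	Y	4.49	--	4
Shoc2	Shoc2, leucine rich repeat scaffold protein	--	--	--	--	Y	Y	3.57	--	4
Afap1l2	actin filament associated protein 1-like 2	missense_variant	--	Y	--	--	Y	1.86	--	4
Ablim1	actin-binding LIM protein 1	Nonsynonymous SNP	--	--	Y	Y	--	6.88	--	4
Slc18a2	solute carrier family 18 (vesicular monoamine), member 2	Nonsynonymous SNP	--	--	Y	--	--	1.26	Y	4
Add3	adducin 3 (gamma)	--	--	--	--	--	--	4.94	Y	3
Dusp5	dual specificity phosphatase 5	--	--	--	--	--	--	2.89	Y	3
Bbip1	BBSome interacting protein 1	--	--	--	--	--	y	3.59	--	3
Adra2a	adrenergic receptor, alpha 2a	--	--	Y	--	--	Y	0.06	--	3
Acsl5	acyl-CoA synthetase long-chain family member 5	--	--	--	Y	--	Y	1.62	--	3
Vti1a	vesicle transport through interaction with t-SNAREs 1A	--	--	Y	--	Y	--	2.76	--	3
Tcf7l2	transcription factor 7 like 2, T cell specific, HMG box	--	Y	Y	--	--	--	3.23	--	3
Nrap	nebulin-related anchoring protein	Nonsynonymous SNP	--	Y	--	--	--	8.40	--	3
Casp7	caspase 7	--	--	--	--	--	--	3.68	Y	3
Nhlrc2	NHL repeat containing 2	--	--	Y	Y	--	--	3.83	--	3
Gfra1	glial cell line derived neurotrophic factor family receptor alpha 1	Splice site mutation	--	Y	--	--	--	2.63	--	3
Pnliprp2	pancreatic lipase-related protein 2	Nonsynonymous SNP	--	Y	Y	--	--	0.01	--	3
Rab11fip2	RAB11 family interacting protein 2 (class I)	--	--	--	Y	Y	--	2.30	--	3
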