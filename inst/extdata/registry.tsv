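name	family	centering	correlation	branch_tag
parker.original	NC	median	spearman	conventional
genefu.scale	NC	median	pearson	conventional
PCAPAM50	NC	pca_guided	spearman	conventional
cIHC	NC	cihc	spearman	deviated
cIHC.itr	NC	cihc_iterative	spearman	deviated
genefu.robust	NC	robust_scale	pearson	deviated
ssBC	NC	ssbc_quantile	spearman	subtype
ssBC.v2	NC	ssbc_quantile	spearman	subtype
AIMS	SSP	-	-	ssp
sspbc	SSP	-	-	ssp
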