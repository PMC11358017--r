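macrophage_demo_synthetic	synthetic placeholder macrophage signature (not a published gene list)	CD68	CD163	MRC1	MSR1	CSF1R	ITGAM	P2RY6	CD14	FCGR1A	MERTK
cd8_t_cell_demo_synthetic	synthetic placeholder CD8 T cell signature (not a published gene list)	CD8A	CD8B	GZMB	PRF1	IFNG	CD3D	CD3E	KLRG1	NKG7	CCL5
metabolic_demo_synthetic	synthetic placeholder metabolic gene list (not the curated 1321-gene list)	CDA	UPP1	UCK2	NT5E	CTPS1	TYMS	DPYD	UMPS	CMPK1	NME1	ADA	PNP
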