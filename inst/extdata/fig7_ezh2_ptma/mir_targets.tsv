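# Strong-evidence (functionally validated) miRNA-target interactions for
# the EZH2/PTMA example network.
mirna_id	target_symbol	confidence	cwcs	evidence_methods
hsa-miR-26a-5p	EZH2	observed	NA	reporter_assay;western_blot;qpcr
hsa-miR-101-3p	EZH2	observed	NA	reporter_assay;western_blot;qpcr
hsa-miR-1-3p	PTMA	observed	NA	reporter_assay;qpcr
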