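# Strong-evidence miRNA-target interactions for the TP53/CCND1/CTNNB1
# hub-gene example: three validated regulators of TP53 (miR-125b-5p,
# miR-34a-5p, miR-30a-5p), two of CCND1, one of CTNNB1.
mirna_id	target_symbol	confidence	cwcs	evidence_methods
hsa-miR-125b-5p	TP53	observed	NA	reporter_assay;western_blot;qpcr
hsa-miR-34a-5p	TP53	observed	NA	reporter_assay;qpcr
hsa-miR-30a-5p	TP53	observed	NA	reporter_assay;western_blot
hsa-miR-193a-3p	CCND1	observed	NA	reporter_assay;qpcr
hsa-miR-195-5p	CCND1	observed	NA	reporter_assay;western_blot;qpcr
hsa-miR-200a-3p	CTNNB1	observed	NA	reporter_assay;qpcr
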