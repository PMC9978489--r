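# Literature-curated example: direction calls for the six-axis EZH2/PTMA
# ceRNA network reported in gallbladder cancer (anchors up, their miRNAs
# down, the sponging lncRNAs up).
molecule_id	class	study_id	direction
EZH2	mRNA	literature	up
PTMA	mRNA	literature	up
hsa-miR-26a-5p	miRNA	literature	down
hsa-miR-101-3p	miRNA	literature	down
hsa-miR-1-3p	miRNA	literature	down
TUG1	lncRNA	literature	up
MALAT1	lncRNA	literature	up
NEAT1	lncRNA	literature	up
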