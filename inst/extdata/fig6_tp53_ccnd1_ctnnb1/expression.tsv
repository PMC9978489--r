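# Literature-curated example: direction calls for the hub-gene ceRNA
# networks around TP53, CCND1 and CTNNB1 in gallbladder cancer. The
# up/down assignment follows the sponge pattern of the reported axes
# (anchors up — TP53 is reported overexpressed in most gallbladder
# tumors — their miRNAs down, the sponging lncRNAs up).
molecule_id	class	study_id	direction
TP53	mRNA	literature	up
CCND1	mRNA	literature	up
CTNNB1	mRNA	literature	up
hsa-miR-125b-5p	miRNA	literature	down
hsa-miR-34a-5p	miRNA	literature	down
hsa-miR-30a-5p	miRNA	literature	down
hsa-miR-193a-3p	miRNA	literature	down
hsa-miR-195-5p	miRNA	literature	down
hsa-miR-200a-3p	miRNA	literature	down
MALAT1	lncRNA	literature	up
TUG1	lncRNA	literature	up
NEAT1	lncRNA	literature	up
PVT1	lncRNA	literature	up
H19	lncRNA	literature	up
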