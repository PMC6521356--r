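id	name	compartment	initial_nM	role	module
NRG	Neuregulin	cytoplasm	0	ligand	canonical
HER4	HER4 receptor	cytoplasm	3	receptor	canonical
HER2_3	HER2/HER3 partner receptor pool	cytoplasm	4	receptor	canonical
JAK	JAK2 kinase	cytoplasm	3	kinase	canonical
HER4_JAK	HER4-JAK2 complex	cytoplasm	0	complex	canonical
aHER4_JAK	Activated HER4-JAK2 complex	cytoplasm	0	complex	canonical
STATc	Cytoplasmic STAT5	cytoplasm	10	transcription_factor	canonical
STATc_p	Phosphorylated cytoplasmic STAT5	cytoplasm	0	transcription_factor	canonical
STATdim_c	Cytoplasmic STAT5 dimer	cytoplasm	0	complex	canonical
SHP	SHP phosphatase	cytoplasm	1.5	phosphatase	canonical
PPX	PPX phosphatase	cytoplasm	1	phosphatase	canonical
aHER4_JAK_SHP	Active receptor-SHP complex	cytoplasm	0	complex	canonical
SOCS	SOCS protein	cytoplasm	0	protein	canonical
SOCS_HER4_JAK	SOCS-bound receptor complex	cytoplasm	0	complex	canonical
SOCS_mRNA_n	SOCS mRNA (nucleus)	nucleus	0	mRNA	canonical
SOCS_mRNA_c	SOCS mRNA (cytoplasm)	cytoplasm	0	mRNA	canonical
casein_mRNA_n	beta-casein mRNA (nucleus)	nucleus	0	mRNA	canonical
casein_mRNA_c	beta-casein mRNA (cytoplasm)	cytoplasm	0	mRNA	canonical
casein	beta-casein protein	cytoplasm	0	protein	canonical
STATdim_n	Nuclear STAT5 dimer	nucleus	0	transcription_factor	canonical
PPN	Nuclear phosphatase PPN	nucleus	0.6	phosphatase	canonical
STATdim_PPN	Nuclear STAT5 dimer-PPN complex	nucleus	0	complex	canonical
STATn	Nuclear unphosphorylated STAT5	nucleus	0	transcription_factor	canonical
HET	HER4 heterodimer (unliganded)	cytoplasm	0	complex	heterodimerization
HET_L	Ligand-bound HER4 heterodimer	cytoplasm	0	complex	heterodimerization
s80	HER4 s80/4ICD fragment (IFNR)	cytoplasm	0	complex	jak_independent
s80_a	Activated HER4 s80 fragment	cytoplasm	0	complex	jak_independent
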