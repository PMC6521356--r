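parameter	value	unit	module	description
kfR01	0.1	nM-1.h-1	canonical	HER4 JAK Binding (forward)
krR01	0.2	h-1	canonical	HER4 JAK Binding (reverse)
kfR02	1.0	nM-1.h-1	canonical	HER4 JAK Ligand Activation by NRG
kR06	5.0	nM-1.h-1	canonical	STATc Phosphorylation JAK Dependent
kfR10	2.0	nM-1.h-1	canonical	STAT Dimerization
kR15	1.2	h-1	canonical	STAT Dimer Nuclear Translocation
kR17	2.0	nM-1.h-1	canonical	STATc Dephosphorylation by PPX
kfR19	1.0	nM-1.h-1	canonical	Nuclear STAT Dimer PPN Binding
kR20	2.0	h-1	canonical	Nuclear STAT Dimer Dephosphorylation
kR21	1.0	h-1	canonical	STAT Nuclear Export
V_transc	10.0	nM.h-1	canonical	Transcription Half-Maximum rate (Hill Vmax)
K_transc	10.0	nM	canonical	Transcription Equilibrium Coefficient (Hill K)
n_transc	2.0	dimensionless	canonical	Transcription Hill Coefficient
kR24	1.5	h-1	canonical	mRNA Nuclear Export (SOCS)
kR25	1.0	h-1	canonical	Translation
kR26	0.6	h-1	canonical	mRNA Degradation (SOCS)
kfR27	1.5	nM-1.h-1	canonical	Active HER4 JAK SHP Binding
kR28	2.5	h-1	canonical	Receptor Dephosphorylation via SHP
SOCS_Binding_Rate	2.0	nM-1.h-1	canonical	SOCS Mediated negative feedback (binding)
kfR29	4.0	nM-1.h-1	canonical	STATc SOCS HER4 JAK SHP Binding (complex turnover)
kR31	0.3	h-1	canonical	SOCS Degradation
V_basal_transc	0.05	nM.h-1	canonical	Transcription Basal Casein (HC/GR-driven, NRG independent)
kR45	6.0	h-1	canonical	mRNA Nuclear Export Casein
kR46	3.0	h-1	canonical	mRNA degradation rate (casein)
kfR41	0.012	nM-2.h-1	heterodimerization	HER4 Heterodimerization (ligand dependent)
kfR42	0.02	nM-1.h-1	heterodimerization	HER4 Heterodimerization Constitutive
kfR43	0.4	nM-1.h-1	heterodimerization	HER4 Heterodimer Ligand Binding
kfR36	0.003	nM-1.h-1	jak_independent	IFNR (HER4 s80) Formation
kR37	0.08	h-1	jak_independent	IFNR (HER4 s80) Activation
kR39	0.5	nM-1.h-1	jak_independent	STATc Phosphorylation JAK independent
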