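accession	description	gene	score	empai
O95218	Zinc finger Ran-binding domain-containing protein 2	ZRANB2	39	0.21
Q9NX65	Zinc finger and SCAN domain-containing protein 32	ZSCAN32	26	0.05
Q9UBQ0	Vacuolar protein sorting-associated protein 29	VPS29	56	0.66
Q14376	UDP-glucose 4-epimerase	GALE	38	0.1
Q12888	Tumor suppressor p53-binding protein 1	TP53BP1	28	0.02
O14773	Tripeptidyl-peptidase 1	TPP1	76	0.06
Q13428	Treacle protein	TCOF1	27	0.02
P04183	Thymidine kinase, cytosolic	TK1	24	0.15
Q9NXG2	THUMP domain-containing protein 1	THUMPD1	58	0.09
Q8WW59	SPRY domain-containing protein 4	SPRYD4	39	0.16
P63151	Serine/threonine-protein phosphatase 2A 55 kDa regulatory subunit B alpha isoform	PPP2R2A	87	0.07
Q9NVA2	Septin-11	SEPT11	29	0.08
O00764	Pyridoxal kinase	PDXK	59	0.11
Q16740	ATP-dependent Clp protease proteolytic subunit, mitochondrial	CLPP	67	0.26
Q9Y4X5	E3 ubiquitin-protein ligase ARIH1	ARIH1	29	0.06
O15460	Prolyl 4-hydroxylase subunit alpha-2	P4HA2	41	0.12
P40261	Nicotinamide N-methyltransferase	NNMT	46	0.27
P19105	Myosin regulatory light chain 12A	MYL12A	200	2.45
Q16539	Mitogen-activated protein kinase 14	MAPK14	82	0.19
Q9UNF1	Melanoma-associated antigen D2	MAGED2	238	0.18
P50213	Isocitrate dehydrogenase [NAD] subunit alpha, mitochondrial	IDH3A	64	0.2
P05161	Ubiquitin-like protein ISG15	ISG15	34	0.21
O00629	Importin subunit alpha-3	KPNA4	49	0.06
Q8WTS6	Histone-lysine N-methyltransferase SETD7	SETD7	42	0.09
P06737	Glycogen phosphorylase, liver form	PYGL	40	0.04
P30712	Glutathione S-transferase theta-2	GSTT2	96	0.14
P47755	F-actin-capping protein subunit alpha-2	CAPZA2	109	0.38
P52907	F-actin-capping protein subunit alpha-1	CAPZA1	118	0.54
P41091	Eukaryotic translation initiation factor 2 subunit 3	EIF2S3	43	0.07
O95571	Persulfide dioxygenase ETHE1, mitochondrial	ETHE1	35	0.13
Q9BVJ7	Dual specificity protein phosphatase 23	DUSP23	50	0.23
P52564	Dual specificity mitogen-activated protein kinase kinase 6	MAP2K6	29	0.1
Q14691	DNA replication complex GINS protein PSF1	GINS1	24	0.16
Q3LXA3	Bifunctional ATP-dependent dihydroxyacetone kinase/FAD-AMP lyase (cyclizing)	DAK	45	0.06
P21291	Cysteine and glycine-rich protein 1	CSRP1	47	0.39
Q99627	COP9 signalosome complex subunit 8	COPS8	69	0.35
Q9UBW8	COP9 signalosome complex subunit 7a	COPS7A	46	0.12
P61201	COP9 signalosome complex subunit 2	COPS2	136	0.23
Q07021	Complement component 1 Q subcomponent-binding protein, mitochondrial	C1QBP	648	1.74
Q9NT62	Ubiquitin-like-conjugating enzyme ATG3	ATG3	58	0.1
Q9BZZ5	Apoptosis inhibitor 5	API5	173	0.13
P12814	Alpha-actinin-1	ACTN1	1345	1.76
P11766	Alcohol dehydrogenase class 3	ADH5	78	0.19
P36404	ADP-ribosylation factor-like protein 2	ARL2	38	0.4
P40616	ADP-ribosylation factor-like protein 1	ARL1	39	0.19
P84077	ADP-ribosylation factor 1	ARF1	99	0.66
P00813	Adenosine deaminase	ADA	35	0.09
Q9BTT0	Acidic leucine-rich nuclear phosphoprotein 32 family member E	ANP32E	169	0.41
P84098	60S ribosomal protein L19	RPL19	38	0.16
P61586	Transforming protein RhoA	RHOA	32	0.17
Q07960	Rho GTPase-activating protein 1	ARHGAP1	63	0.07
Q14657	EKC/KEOPS complex subunit LAGE3	LAGE3	34	0.26
Q96IU4	Alpha/beta hydrolase domain-containing protein 14B	ABHD14B	67	0.17
P39687	Acidic leucine-rich nuclear phosphoprotein 32 family member A	ANP32A	286	1.38
O75607	Nucleoplasmin-3	NPM3	33	0.2
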