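accession	description	gene	score	fc_40min	fc_2h	fc_5h	sig_40min	sig_2h	sig_5h	direction	chem_overlap
Q14566	DNA replication licensing factor MCM6	MCM6	76.01	-4.2	-1.1	-2	TRUE	FALSE	FALSE	down	TRUE
Q14764	Major vault protein	MVP	88.9	-1.2	-1.9	-2.6	FALSE	FALSE	TRUE	down	FALSE
P35579	Myosin-9	MYH9	166.85	-1.7	-2.9	-1.6	FALSE	TRUE	FALSE	down	TRUE
P61160	Actin-related protein 2	ACTR2	60.97	-2.6	-1.4	-1.8	TRUE	FALSE	FALSE	down	FALSE
Q02338	D-beta-hydroxybutyrate dehydrogenase, mitochondrial	BDH1	71.17	-1.7	-1.4	-2.6	FALSE	FALSE	TRUE	down	FALSE
P20290	Transcription factor BTF3	BTF3	62.09	1.2	-2.9	-1.5	FALSE	TRUE	FALSE	down	FALSE
Q7L1Q6	Basic leucine zipper and W2 domain-containing protein 1	BZW1	95.07	-1.3	-3.8	-2.3	FALSE	TRUE	FALSE	down	FALSE
P17655	Calpain-2 catalytic subunit	CAPN2	101.09	-1.3	-3.1	-1.9	FALSE	TRUE	FALSE	down	FALSE
A8K010	Putative uncharacterized protein C6orf176	C6orf176	33.72	-1.1	-3.3	-1.6	FALSE	TRUE	FALSE	down	FALSE
P53618	Coatomer subunit beta	COPB1	64.4	-2.9	-1.5	-1.4	TRUE	FALSE	FALSE	down	FALSE
O60888	Protein CutA	CUTA	62.42	1.2	-2.2	-2.9	FALSE	FALSE	TRUE	down	FALSE
O14976	Cyclin-G-associated kinase	GAK	47.67	-3.4	-3.8	-2.9	TRUE	TRUE	TRUE	down	FALSE
O95395	Beta-1,3-galactosyl-O-glycosyl-glycoprotein beta-1,6-N-acetylglucosaminyltransferase 3	GCNT3	59.62	-3.2	-1.2	-1.6	TRUE	FALSE	FALSE	down	FALSE
P52306	Rap1 GTPase-GDP dissociation stimulator 1	RAP1GDS1	66.74	-1.2	-3	-1.1	FALSE	TRUE	FALSE	down	FALSE
O15228	Dihydroxyacetone phosphate acyltransferase	GNPAT	46.58	-4.5	-3.1	-1.9	TRUE	TRUE	FALSE	down	FALSE
Q86Y56	HEAT repeat-containing protein 2	HEATR2	63.07	-1.5	-5	-1.4	FALSE	TRUE	FALSE	down	FALSE
Q6YP21	Kynurenine-oxoglutarate transaminase 3	CCBL2	39.9	1.7	OFF	1.5	FALSE	TRUE	FALSE	down	FALSE
P43243	Matrin-3	MATR3	269.16	1	-1.2	-4.5	FALSE	FALSE	TRUE	down	FALSE
O75439	Mitochondrial-processing peptidase subunit beta	PMPCB	99.73	-2.9	1.2	-1.1	TRUE	FALSE	FALSE	down	FALSE
O43847	Nardilysin	NRD1	41.16	-1.3	-2.9	1.6	FALSE	TRUE	FALSE	down	TRUE
O15270	Serine palmitoyltransferase 2	SPTLC2	62.71	-3.2	-2	-2.5	TRUE	FALSE	TRUE	down	FALSE
P29122	Proprotein convertase subtilisin/kexin type 6	PCSK6	30.52	-1.3	-1.5	-16.7	FALSE	FALSE	TRUE	down	FALSE
P00491	Purine nucleoside phosphorylase	PNP	91.96	-2	-5.6	1.7	FALSE	TRUE	FALSE	down	FALSE
P25787	Proteasome subunit alpha type 2	PSMA2	75.42	1.6	-2.9	1	FALSE	TRUE	FALSE	down	TRUE
O14818	Proteasome subunit alpha type 7	PSMA7	103.36	-1.3	-2.8	-1.1	FALSE	TRUE	FALSE	down	FALSE
Q13813	Spectrin alpha chain, nonerythrocytic 1	SPTAN1	112.76	-1.6	-3.1	-1.6	FALSE	TRUE	FALSE	down	FALSE
Q9UL25	Ras-related protein Rab-21	RAB21	129.33	-2.6	1.1	-1.1	TRUE	FALSE	FALSE	down	FALSE
Q9NV58	E3 ubiquitin-protein ligase RNF19A	RNF19A	31.17	-1.4	-1.8	-4.8	FALSE	FALSE	TRUE	down	FALSE
P62081	40S ribosomal protein S7	RPS7	65.3	-4.2	-3.8	-2.6	TRUE	TRUE	TRUE	down	FALSE
Q96FQ6	Protein S100-A16	S100A16	78	-2.6	-1.4	1	TRUE	FALSE	FALSE	down	FALSE
P63208	S-phase kinase-associated protein 1	SKP1	72.23	-7.1	-3.1	1.2	TRUE	TRUE	FALSE	down	FALSE
O00193	Small acidic protein	SMAP	74.25	-1.5	-2.6	-1.3	FALSE	TRUE	FALSE	down	FALSE
Q96JX3	Protein SERAC1	SERAC1	32.13	-1.1	1.3	-2.5	FALSE	FALSE	TRUE	down	FALSE
Q9Y5M8	Signal recognition particle receptor subunit beta	SRPRB	54.95	-1.7	-1.1	-2.9	FALSE	FALSE	TRUE	down	FALSE
Q96I99	Succinyl-CoA ligase [GDP-forming] subunit beta, mitochondrial	SUCLG2	85.7	-1.5	-2.4	-2.4	FALSE	FALSE	TRUE	down	FALSE
O75223	Gamma-glutamylcyclotransferase	GGCT	37.33	1.1	2	3.8	FALSE	FALSE	TRUE	up	FALSE
P61758	Prefoldin subunit 3	VBP1	152.64	2.1	2.2	2.5	FALSE	FALSE	TRUE	up	FALSE
Q9BWD1	Acetyl-CoA acetyltransferase, cytosolic	ACAT2	69.2	2.5	2	3.2	FALSE	FALSE	TRUE	up	FALSE
Q86TX2	Acyl-coenzyme A thioesterase 1	ACOT1	73.32	2.8	1.6	2.4	TRUE	FALSE	TRUE	up	FALSE
P02647	Apolipoprotein A-I	APOA1	76.16	1.9	2.7	-1.1	FALSE	TRUE	FALSE	up	FALSE
O00192	Armadillo repeat protein deleted in velocardiofacial syndrome	ARVCF	46	ON	ON	ON	TRUE	TRUE	TRUE	up	FALSE
Q9NYF8	Bcl-2-associated transcription factor 1	BCLAF1	86.18	1	ON	ON	FALSE	TRUE	TRUE	up	FALSE
O14523	C2 domain-containing protein 2-like	C2CD2L	31.3	2.9	1.7	2	TRUE	FALSE	FALSE	up	FALSE
P60953	Cell division control protein 42 homolog	CDC42	52.58	2.3	1.5	3.1	FALSE	FALSE	TRUE	up	FALSE
Q9UJS0	Calcium-binding mitochondrial carrier protein Aralar2	SLC25A13	57.95	2.4	3.4	1.9	FALSE	TRUE	FALSE	up	FALSE
O43809	Cleavage and polyadenylation specificity factor subunit 5	NUDT21	70.35	1.2	-1.7	2.5	FALSE	FALSE	TRUE	up	FALSE
Q96C86	Scavenger mRNA-decapping enzyme DcpS	DCPS	70.59	1.5	2.1	2.4	FALSE	FALSE	TRUE	up	TRUE
Q5TDH0	Protein DDI1 homolog 2	DDI2	31.55	1	ON	ON	FALSE	TRUE	TRUE	up	FALSE
P18858	DNA ligase 1	LIG1	49.53	2.3	2.2	2.6	FALSE	FALSE	TRUE	up	FALSE
Q5JZY3	Ephrin type A receptor 10	EPHA10	37.22	ON	ON	ON	TRUE	TRUE	TRUE	up	FALSE
O76003	Glutaredoxin-3	GLRX3	50.31	3.2	1.8	2.4	TRUE	FALSE	TRUE	up	FALSE
Q14103	Heterogeneous nuclear ribonucleoprotein D0	HNRNPD	138.39	1.4	3	1.4	FALSE	TRUE	FALSE	up	FALSE
Q96P70	Importin-9	IPO9	88.04	3.9	2.9	2.9	TRUE	TRUE	TRUE	up	TRUE
P33176	Kinesin-1 heavy chain	KIF5B	102.25	4.3	3.6	5.1	TRUE	TRUE	TRUE	up	TRUE
P49006	MARCKS-related protein	MARCKSL1	112.06	ON	ON	1	TRUE	TRUE	FALSE	up	FALSE
Q9H3R2	Mucin-13	MUC13	68.36	1.8	4.2	1.9	FALSE	TRUE	FALSE	up	FALSE
Q7Z406	Myosin-14	MYH14	90.59	-1.1	9.7	-1.9	FALSE	TRUE	FALSE	up	FALSE
Q9NX40	OCIA domain-containing protein 1	OCIAD1	87.8	2.6	2.9	2.3	TRUE	TRUE	FALSE	up	FALSE
Q15102	Platelet-activating factor acetylhydrolase IB subunit gamma	PAFAH1B3	84.5	2.4	62.4	1.6	FALSE	TRUE	FALSE	up	FALSE
O43252	Bifunctional 3'-phosphoadenosine 5'-phosphosulfate synthetase 1	PAPSS1	51.9	1	1	ON	FALSE	FALSE	TRUE	up	FALSE
P36871	Phosphoglucomutase-1	PGM1	105.24	3.3	-2.2	2.2	TRUE	FALSE	FALSE	up	FALSE
P35232	Prohibitin	PHB	90.52	8.4	4.7	3.2	TRUE	TRUE	TRUE	up	FALSE
Q9UHJ6	Sedoheptulokinase	SHPK	59.09	1	1	ON	FALSE	FALSE	TRUE	up	FALSE
P52788	Spermine synthase	SMS	60.56	-1.2	2.1	3.2	FALSE	FALSE	TRUE	up	FALSE
Q01082	Spectrin beta chain, brain 1	SPTBN1	63.84	ON	ON	ON	TRUE	TRUE	TRUE	up	FALSE
Q9Y3F4	Serine-threonine kinase receptor-associated protein	STRAP	80.3	2.9	3.7	4.5	TRUE	TRUE	TRUE	up	FALSE
P26640	Valyl-tRNA synthetase	VARS	54.77	1.7	3	3.5	FALSE	TRUE	TRUE	up	TRUE
Q86VP1	Tax1-binding protein 1	TAX1BP1	31.29	2.3	11.7	1.2	FALSE	TRUE	FALSE	up	FALSE
Q9HD45	Transmembrane 9 superfamily member 3	TM9SF3	71.54	1.5	3.1	-1.8	FALSE	TRUE	FALSE	up	FALSE
P55327	Tumor protein D52	TPD52	64.69	5.9	1.8	1.8	TRUE	FALSE	FALSE	up	FALSE
P38606	V-type proton ATPase catalytic subunit A	ATP6V1A	66.31	-1.2	4.4	2.8	FALSE	TRUE	TRUE	up	FALSE
P45880	Voltage-dependent anion-selective channel protein 2	VDAC2	59.14	2.1	4	2	FALSE	TRUE	FALSE	up	FALSE
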