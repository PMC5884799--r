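cluso	gene	name	group_regulation	group_log2fc	group_occurrences	group_opposite_n	virus_regulation	virus_log2fc	virus_occurrences	virus_opposite_n	inflammation_regulation	inflammation_log2fc	inflammation_occurrences	inflammation_opposite_n	autoimmune_regulation	autoimmune_log2fc	autoimmune_occurrences	autoimmune_opposite_n
B0717	ANKRD10	Ankyrin repeat domain protein 10	up	2.21	4	0	ns	NA	NA	0	ns	NA	NA	0	ns	NA	NA	0
B0384	ADD2	Beta-adducin	up	2.12	3	0	ns	NA	NA	0	ns	NA	NA	0	ns	NA	NA	0
BA289	SLC8A1	Sodium/calcium exchanger 1 precursor	up	3.11	3	1	ns	NA	NA	0	ns	NA	NA	0	down	-1.24	1	0
B9374	MALAT1	Metastasis associated lung adenocarcinoma transcript 1 protein	down	-1.92	3	1	ns	NA	NA	0	ns	NA	NA	0	down	-1.66	2	0
B1814	C1ORF228	Uncharacterized protein C1ORF228	up	1.28	3	0	down	-1.27	1	0	ns	NA	NA	0	up	1.66	1	0
BF644	SSTR2	Somatostatin receptor type 2	down	-2.32	3	0	ns	NA	NA	0	ns	NA	NA	0	ns	NA	NA	0
B5523	F5	Coagulation factor V precursor	down	-1.4	3	1	ns	NA	NA	0	ns	NA	NA	0	ns	NA	NA	0
B3266	CNTNAP2	Contactin-associated protein-like 2 precursor	down	-3.21	3	1	down	-1.25	1	0	down	-1.08	1	0	up	2.03	1	0
BG121	TAF9B	Transcription initiation factor TFIID subunit 9B	up	1.91	3	0	ns	NA	NA	0	ns	NA	NA	0	ns	NA	NA	0
B9009	LPP	Lipoma preferred partner	up	1.48	3	1	down	-1.64	1	0	ns	NA	NA	0	ns	NA	NA	0
BB904	PAWR	Prostate apoptosis response protein PAR-4	down	-2.09	3	0	ns	NA	NA	0	ns	NA	NA	0	ns	NA	NA	0
BD727	RIF1	Telomere-associated protein RIF1	down	-1.64	3	0	ns	NA	NA	0	ns	NA	NA	0	up	1.38	1	0
BA240	PDE4DIP	Myomegalin	up	1.27	3	0	ns	NA	NA	0	up	1.11	1	0	ns	NA	NA	0
BF121	SMAD4	Mothers against decapentaplegic homolog 4	up	1.56	3	0	ns	NA	NA	0	ns	NA	NA	0	up	1.2	1	0
BJ537	DKK3	Dickkopf-related protein 3	up	1.86	3	0	ns	NA	NA	0	ns	NA	NA	0	ns	NA	NA	0
B9548	MDM4	MDM4 P53 binding protein homolog	up	1.58	3	1	ns	NA	NA	0	ns	NA	NA	0	ns	NA	NA	0
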