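cluso	gene	name	group_regulation	group_log2fc	group_occurrences	group_opposite_n	virus_regulation	virus_log2fc	virus_occurrences	virus_opposite_n	inflammation_regulation	inflammation_log2fc	inflammation_occurrences	inflammation_opposite_n	autoimmune_regulation	autoimmune_log2fc	autoimmune_occurrences	autoimmune_opposite_n
BE141	RSAD2	Radical S-Adenosyl methionine domain-containing protein 2	up	2.52	14	1	ns	NA	NA	0	up	1.35	1	0	up	2.36	4	0
BA153	MX1	Interferon-induced GTP-binding protein MX1	up	1.92	11	1	ns	NA	NA	0	ns	NA	NA	0	up	1.66	4	0
B7528	IFI44L	Interferon-induced protein 44-like	up	2.99	10	1	ns	NA	NA	0	ns	NA	NA	0	up	2.25	7	0
B7546	IFI27	Interferon-alpha inducible protein 27	up	4.05	10	1	up	2.25	2	0	ns	NA	NA	0	up	4.04	5	0
BI124	BIRC4BP	XIAP associated factor-1	up	1.54	10	1	ns	NA	NA	0	ns	NA	NA	0	up	1.54	3	0
B7105	HERC5	Probable E3 ubiquitin-protein ligase HERC5	up	1.96	10	1	ns	NA	NA	0	ns	NA	NA	0	up	1.73	6	0
B7896	ISG15	Ubiquitin-like protein ISG15	up	2.15	10	1	up	1.33	1	0	ns	NA	NA	0	up	1.98	6	0
BF209	SIGLEC1	Sialoadhesin precursor	up	2.83	10	1	up	1.95	1	0	ns	NA	NA	0	up	2.88	2	0
BF513	SPATS2L	SPATS2-like protein	up	1.8	9	1	ns	NA	NA	0	ns	NA	NA	0	up	1.76	4	0
BC522	PLSCR1	Phospholipid scramblase 1	up	1.32	9	1	ns	NA	NA	0	up	1.10	2	0	up	1.58	1	0
BH558	USP18	Ubl carboxyl-terminal hydrolase 18	up	2.58	9	1	ns	NA	NA	0	ns	NA	NA	0	up	2.41	4	0
B4753	EIF2AK2	Eukaryotic translation initiation factor 2-alpha kinase 2	up	1.35	9	1	ns	NA	NA	0	ns	NA	NA	0	up	0.15	4	2
B7547	IFI44	Interferon-induced protein 44	up	1.69	9	1	ns	NA	NA	0	ns	NA	NA	0	up	1.88	5	0
B7549	IFIH1	Interferon-induced helicase C domain-containing protein 1	up	1.44	9	1	ns	NA	NA	0	ns	NA	NA	0	up	1.1	4	0
BB257	OAS2	2'-5'-oligoadenylate synthase 2	up	1.56	9	1	ns	NA	NA	0	ns	NA	NA	0	up	1.63	5	0
B5174	EPSTI1	Epithelial stromal interaction protein 1	up	1.69	9	1	up	1.26	1	0	up	1.12	2	0	up	2	2	0
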