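genome_id	taxon_label	domain	source	genome_size_bp	marker_copies	marker_copies_estimated
KG1	Bacillus sp. KG1	bacteria	MAG	3100000	10	yes
KG2	Bacillus sp. KG2	bacteria	MAG	3100000	8	yes
KG3	Bacillus sp. KG3	bacteria	MAG	4500000	9	yes
KG4	Corynebacterium sp. KG4	bacteria	MAG	3000000	5	yes
KG5	Staphylococcus sp. KG5	bacteria	MAG	3100000	6	yes
KG6	Halomonas sp. KG6	bacteria	MAG	3000000	4	yes
KG7	Virgibacillus sp. KG7	bacteria	MAG	3600000	8	yes
KG8	Alteromonadaceae sp. KG8	bacteria	MAG	4900000	3	yes
KG9	Idiomarinaceae sp. KG9	bacteria	MAG	4200000	4	yes
KG10	Micrococcaceae sp. KG10	bacteria	MAG	3100000	6	yes
KG11	Tetragenococcus sp. KG11	bacteria	isolate	2400000	5	yes
KG12	Tetragenococcus sp. KG12	bacteria	isolate	2500000	5	yes
KG13	Chromohalobacter sp. KG13	bacteria	isolate	3500000	5	yes
KG14	Marinobacter sp. KG14	bacteria	isolate	3500000	3	yes
KG15	Aspergillus sp. KG15	fungi	isolate	38000000	3	yes
KG16	Wickerhamomyces sp. KG16	fungi	isolate	23900000	1	no
C11	Debaryomyces sp. C11	fungi	isolate	24500000	5	no
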