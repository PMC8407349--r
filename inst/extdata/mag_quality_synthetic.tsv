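genome_id	completeness	contamination
KG1	98.2	1.3
KG2	96.5	0.8
KG3	94.1	2.2
KG4	92.7	3.5
KG5	99.0	0.4
KG6	97.3	1.9
KG7	90.0	5.0
KG8	93.8	2.7
KG9	95.6	1.2
KG10	91.4	4.4
BIN11	89.9	2.0
BIN12	75.2	1.1
BIN13	95.0	6.7
BIN14	62.4	12.9
BIN15	88.0	5.1
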