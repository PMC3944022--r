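patient_id	clustering_group	crc_mutations	clm_mutations	shared_pct
185	remotely_related	101	34	0
250	remotely_related	102	890	0
262	remotely_related	95	916	0.2
353	remotely_related	66	77	52.1
381	remotely_related	16	84	3.1
526	remotely_related	44	971	0
721	remotely_related	113	819	0.1
278	most_closely_related	72	65	53.9
413	most_closely_related	55	63	43.9
503	most_closely_related	60	65	38.9
509	most_closely_related	71	98	30
523	most_closely_related	90	101	36.4
627	most_closely_related	44	39	45.6
707	most_closely_related	93	81	35.9
718	most_closely_related	58	69	46
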