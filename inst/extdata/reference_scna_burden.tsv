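patient_id	role	one_copy_gain	one_copy_loss	high_copy_gain	homozygous_loss	loh	total_scna	somatic_mutations
185	CRC	837	271	135	92	17	1335	101
185	CLM	829	65	0	0	1	894	34
250	CRC	2538	1728	110	0	12	4376	102
250	CLM	3334	2611	289	132	164	6366	890
262	CRC	1241	875	10	0	0	2126	95
262	CLM	1121	1601	72	42	146	2836	916
278	CRC	745	378	27	139	180	1289	72
278	CLM	1102	533	24	132	62	1791	65
353	CRC	289	67	9	7	0	372	66
353	CLM	1634	1089	0	0	0	2723	77
381	CRC	2339	578	2	0	0	2919	16
381	CLM	683	392	15	0	0	1090	84
413	CRC	389	643	4	3	0	1039	55
413	CLM	351	211	23	0	0	585	63
503	CRC	1493	470	19	0	1	1982	60
503	CLM	1103	2187	26	0	3	3316	65
509	CRC	1290	508	0	0	0	1798	71
509	CLM	240	98	14	0	6	352	98
523	CRC	792	256	16	0	1	1064	90
523	CLM	148	84	13	0	7	245	101
526	CRC	107	107	0	0	0	214	44
526	CLM	167	281	25	43	145	516	971
627	CRC	1863	1878	0	1	1	3742	44
627	CLM	811	648	0	0	0	1459	39
707	CRC	658	1070	0	0	0	1728	93
707	CLM	1276	565	235	4	80	2080	81
718	CRC	979	330	14	0	0	1323	58
718	CLM	1522	327	113	45	0	2007	69
721	CRC	538	674	0	0	20	1212	113
721	CLM	624	307	44	62	160	1037	819
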