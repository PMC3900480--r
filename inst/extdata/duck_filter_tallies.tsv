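type	E13	E19	E27
total_reads	14881453	13411560	15775148
high_quality	14794223	13376800	15691433
adaptor3_null	1986	6332	1824
insert_null	2620	1613	2281
adaptor5_contaminant	69355	38647	67052
shorter_than_18nt	139922	313055	71069
polyA	225	183	126
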