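name	seq	E13	E19	E27
miR-1	TGGAATGTAAAGAAGTATGTAG	24092	173545	36785
miR-103a-3p	AGCAGCATTGTACAGGGCTATGA	81126	56571	162616
miR-107	AGCAGCATTGTACAGGGCTAT	103914	71695	208096
miR-10a-5p	CAAATTCGTATCTAGGGGAAT	22	17	57
miR-125b-5p	TCCCTGAGACCCTAACTTGTGA	7565	4471	12624
miR-128	TCACAGTGAACCGGTCTCTTTT	55580	45584	106122
miR-130a	CAGTGCAATATTAAAAGGGCAT	11450	6118	21728
miR-133	TTTGGTCCCCTTCAACCAGCT	3715	4912	7043
miR-146b-5p	TGAGAACTGAATTCCATAGGCGTT	5902	12899	13048
miR-148a	TCAGTGCACTACAGAACT	2663	2888	4138
miR-16c	TAGCAGCACGTAAATACTGGAG	10156	11154	20798
miR-181b	AACATTCATTGCTGTCGGTGGGTT	67868	30759	95543
miR-1a-3p	TGGAATGTAAAGAAGTATGTAT	1906033	5142560	2847317
miR-206	TGGAATGTAAGGAAGTGTGTG	769238	1129210	1799320
miR-20b-3p	ACTGTAATGTGGGCACTTA	63	226	95
miR-21-3p	AACAACAGTCGGTAGGCTGTCT	495	112	754
miR-214	TACAGCAGGCACAGACAG	3273	2997	5955
miR-221	AGCTACATTGTCTGCTGGGTTT	15833	13285	32726
miR-222a	AGCTACATCTGGCTACTGGGTCT	7451	25999	15333
miR-23a	ATCACATTGCCAGGGATTTCCA	4008	5680	7679
miR-24	TGGCTCAGTTCAGCAGGAACAGT	3542	5477	7708
miR-26a-5p	TTCAAGTAATCCAGGATAGGCT	14031	22315	24219
miR-29b	TAGCACCATTTGAAATCAGTGT	4	19	27
miR-99a-5p	AACCCGTAGATCCGATCTTGTG	3673	2312	6471
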