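class	uni_E13	tot_E13	uni_E19	tot_E19	uni_E27	tot_E27
total	822873	14580115	389934	13016970	508157	15549081
exon_antisense	161	203	120	259	153	199
exon_sense	19443	86061	8091	62064	12929	106325
intron_antisense	486	6887	263	1262	431	5383
intron_sense	1471	3228	762	1565	1169	3270
miRNA	41574	7115935	33123	10634771	31677	11870273
rRNA	142358	3900741	68824	1233686	77941	1906629
repeat	968	6633	505	1183	807	4185
scRNA	3214	84673	2004	37393	1841	30917
snRNA	5810	44309	2816	12117	4326	34368
snoRNA	2502	18504	1292	7721	2120	20483
tRNA	21767	359561	13311	165488	13485	180390
unannotated	583119	2953380	258823	859461	361278	1386659
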