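category	pgcs	stagex	gscs	cefs
repeat	14624	7395	5	49
unannotated	8394	9335	1248	2181
rRNA	1281	7245	3141	1261
intron_sense	629	566	4	84
tRNA	507	1831	37	554
intron_antisense	320	180	8	51
exon_sense	251	435	49	67
scRNA	92	124	20	44
miRNA	96	448	324	742
snoRNA	75	165	96	79
snRNA	53	151	35	9
exon_antisense	6	28	0	7
Total	26328	27903	4967	5128
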