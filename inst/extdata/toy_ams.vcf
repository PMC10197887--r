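##fileformat=VCFv4.2
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1
toy	28	.	C	T	.	PASS	.	GT	0/1
toy	29	.	G	A	.	PASS	.	GT	0/1
toy	41	.	G	A	.	PASS	.	GT	0/1
toy	52	.	G	A	.	PASS	.	GT	0/1
toy	77	.	C	T	.	PASS	.	GT	0/1
toy	81	.	G	A	.	PASS	.	GT	0/1
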