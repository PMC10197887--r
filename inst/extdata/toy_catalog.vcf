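##fileformat=VCFv4.2
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1
toy	10	.	C	G	.	PASS	.	GT	0/1
toy	25	.	T	C	.	PASS	.	GT	0/1
toy	40	.	G	C	.	PASS	.	GT	0/1
toy	58	.	A	G	.	PASS	.	GT	0/1
toy	77	.	G	T	.	PASS	.	GT	0/1
toy	105	.	C	A	.	PASS	.	GT	0/1
toy	140	.	T	G	.	PASS	.	GT	0/1
toy	180	.	G	A	.	PASS	.	GT	0/1
toy	222	.	A	C	.	PASS	.	GT	0/1
toy	260	.	C	T	.	PASS	.	GT	0/1
toy	120	.	A	AA	.	PASS	.	GT	0/1
toy	200	.	AT	A	.	PASS	.	GT	0/1
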