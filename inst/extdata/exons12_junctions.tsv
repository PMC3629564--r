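chrom	acceptor	donor	strand	count
chr1	1000	950	+	2
chr1	2000	1900	+	3
chr1	2500	2100	+	4
chr1	3000	2900	+	2
chr1	4000	3900	+	1
chr1	4300	4020	+	1
chr1	6000	5900	+	2
chr1	6010	5900	+	1
chr1	6700	6550	+	2
chr1	6700	6560	+	1
chr1	8000	7900	+	5
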