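chr1	test	exon	1000	1100	.	+	.	transcript_id "t1"; gene_id "gX";
chr1	test	exon	2000	2100	.	+	.	transcript_id "t2"; gene_id "gX";
chr1	test	exon	2500	2600	.	+	.	transcript_id "t2"; gene_id "gX";
chr1	test	exon	8000	8100	.	+	.	transcript_id "t2"; gene_id "gX";
chr1	test	exon	3000	3100	.	+	.	transcript_id "t3"; gene_id "gX";
chr1	test	exon	3500	3600	.	+	.	transcript_id "t3"; gene_id "gX";
chr1	test	exon	4000	4020	.	+	.	transcript_id "t4"; gene_id "gX";
chr1	test	exon	4300	14500	.	+	.	transcript_id "t4"; gene_id "gX";
chr1	test	exon	6000	6100	.	+	.	transcript_id "t5"; gene_id "gX";
chr1	test	exon	6500	6550	.	+	.	transcript_id "t5"; gene_id "gX";
chr1	test	exon	6010	6090	.	+	.	transcript_id "t6"; gene_id "gX";
chr1	test	exon	6490	6560	.	+	.	transcript_id "t6"; gene_id "gX";
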