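chrT	toy	gene	1001	6000	.	+	.	gene_id "G1"; transcript_id "G1.t1"; gene_name "G1"; gene_biotype "protein_coding";
chrT	toy	exon	1001	1400	.	+	.	gene_id "G1"; transcript_id "G1.t1"; gene_name "G1"; gene_biotype "protein_coding";
chrT	toy	exon	5001	6000	.	+	.	gene_id "G1"; transcript_id "G1.t1"; gene_name "G1"; gene_biotype "protein_coding";
chrT	toy	gene	201	900	.	-	.	gene_id "G2"; transcript_id "G2.t1"; gene_name "G2"; gene_biotype "protein_coding";
chrT	toy	exon	201	500	.	-	.	gene_id "G2"; transcript_id "G2.t1"; gene_name "G2"; gene_biotype "protein_coding";
chrT	toy	exon	701	900	.	-	.	gene_id "G2"; transcript_id "G2.t1"; gene_name "G2"; gene_biotype "protein_coding";
chrT	toy	gene	12001	13000	.	+	.	gene_id "G3"; transcript_id "G3.t1"; gene_name "G3"; gene_biotype "lncRNA";
chrT	toy	exon	12001	13000	.	+	.	gene_id "G3"; transcript_id "G3.t1"; gene_name "G3"; gene_biotype "lncRNA";
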