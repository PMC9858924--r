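peak	label
chrT:900-1100	prom
chrT:700-950	prom
chrT:7900-8300	enhD
chrT:1050-1150	exon
chrT:750-850	exon
chrT:3000-3500	empty
chrT:8950-9250	enhD
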