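chrT	920	980	R1	0	.	prom
chrT	8000	8200	R2	0	.	enhD
chrT	9000	9150	R3	0	.	enhD
chrT	11000	11200	R4	0	.	CTCF-only
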