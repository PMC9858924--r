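chrT	900	1100
chrT	700	950
chrT	7900	8300
chrT	1050	1150
chrT	750	850
chrT	3000	3500
chrT	8950	9250
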