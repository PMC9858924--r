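Peak1,Peak2,coaccess
chrT_900_1100,chrT_7900_8300,0.6
chrT_700_950,chrT_8950_9250,0.2
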