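CELL-1
CELL-2
CELL-3
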