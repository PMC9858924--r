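%%MatrixMarket matrix coordinate integer general
7 3 12
1 1 1
1 3 1
2 2 1
2 3 1
3 1 1
3 2 1
4 1 1
5 2 1
6 3 1
7 1 1
7 2 1
7 3 1
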