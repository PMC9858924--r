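component	row	col	value
GP	G1	chrT:900-1100	1
GP	G2	chrT:700-950	1
PE	chrT:900-1100	chrT:7900-8300	0.6
GI	G1	chrT:1050-1150	0.98019867330675525
GI	G2	chrT:750-850	0.98039473264669708
P	G1	CELL-1	1
P	G1	CELL-3	1
P	G2	CELL-2	1
P	G2	CELL-3	1
C	G1	CELL-1	0.6
C	G1	CELL-2	0.6
E	G1	CELL-1	0.98019867330675525
E	G2	CELL-2	0.98039473264669708
GAGAM	G1	CELL-1	2.58019867330675525
GAGAM	G1	CELL-2	0.6
GAGAM	G1	CELL-3	1
GAGAM	G2	CELL-2	1.98039473264669708
GAGAM	G2	CELL-3	1
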