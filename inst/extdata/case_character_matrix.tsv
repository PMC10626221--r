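population	cell_type	A	B	C	D	E	F	G	H	I	1	2	3
nPC_1	PC	1	1	1	0	0	0	0	0	0	1	0	0
nPC_2	PC	1	1	0	1	0	0	0	0	0	0	1	0
MB_1	MB	1	0	0	0	1	1	0	0	0	0	0	1
MB_2	MB	1	0	0	0	1	0	0	0	0	0	0	0
neutrophil	neutrophil	0	0	0	0	0	0	1	1	0	0	0	0
eosinophil	eosinophil	0	0	0	0	0	0	1	0	0	0	0	0
erythrocyte	erythrocyte	0	0	0	0	0	0	0	0	1	0	0	0
megakaryocyte	megakaryocyte	0	0	0	0	0	0	0	0	0	0	0	0
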