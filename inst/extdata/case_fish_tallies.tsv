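specimen	probe	pattern	class	positive	scored	ratio_nonpc	ratio_pc
1	TCF3	TCF3 3 copies	TNC	44	200	21	23
1	TCF3	TCF3 3 copies	PC	19	20	NA	NA
3	TCF3	TCF3 3 copies	TNC	23	200	20	3
3	TCF3	TCF3 3 copies	PC	3	10	NA	NA
4	TCF3	TCF3 3 copies	TNC	40	200	37	3
4	TCF3	TCF3 3 copies	PC	3	10	NA	NA
1	CDKN2A	CDKN2A tetrasomy	TNC	25	200	NA	NA
1	CDKN2A	CDKN2A tetrasomy	PC	20	20	NA	NA
3	CDKN2A	CDKN2A tetrasomy	TNC	2	300	NA	NA
3	CDKN2A	CDKN2A tetrasomy	PC	7	20	NA	NA
4	CDKN2A	CDKN2A tetrasomy	TNC	2	300	NA	NA
4	CDKN2A	CDKN2A tetrasomy	PC	0	20	NA	NA
1	RUNX1	RUNX1 3 copies	TNC	23	200	NA	NA
1	RUNX1	RUNX1 3 copies	PC	41	50	NA	NA
3	RUNX1	RUNX1 3 copies	TNC	1	300	NA	NA
3	RUNX1	RUNX1 3 copies	PC	2	10	NA	NA
4	RUNX1	RUNX1 3 copies	TNC	2	300	NA	NA
4	RUNX1	RUNX1 3 copies	PC	1	5	NA	NA
1	MLL	MLL 3 copies	TNC	16	200	NA	NA
1	MLL	MLL 3 copies	PC	18	20	NA	NA
3	MLL	MLL 3 copies	TNC	3	200	NA	NA
3	MLL	MLL 3 copies	PC	3	10	NA	NA
4	MLL	MLL 3 copies	TNC	2	300	NA	NA
4	MLL	MLL 3 copies	PC	2	10	NA	NA
1	PML	PML 3 copies	TNC	18	200	NA	NA
1	PML	PML 3 copies	PC	20	20	NA	NA
3	PML	PML 3 copies	TNC	2	300	NA	NA
3	PML	PML 3 copies	PC	2	10	NA	NA
4	PML	PML 3 copies	TNC	1	300	NA	NA
4	PML	PML 3 copies	PC	2	7	NA	NA
1	CEP8	CEP8 3 copies	TNC	40	200	NA	NA
1	CEP8	CEP8 3 copies	PC	0	20	NA	NA
3	CEP8	CEP8 3 copies	TNC	24	200	NA	NA
3	CEP8	CEP8 3 copies	PC	0	20	NA	NA
4	CEP8	CEP8 3 copies	TNC	49	200	NA	NA
4	CEP8	CEP8 3 copies	PC	0	8	NA	NA
1	20q	20q deletion	TNC	41	200	NA	NA
1	20q	20q deletion	PC	0	20	NA	NA
3	20q	20q deletion	TNC	30	200	NA	NA
3	20q	20q deletion	PC	0	20	NA	NA
4	20q	20q deletion	TNC	61	200	NA	NA
4	20q	20q deletion	PC	0	20	NA	NA
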