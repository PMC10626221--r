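gene	cdna	chrom	pos	ref	alt	consequence	maf	specimen	days	total_depth	alt_depth	vaf
DDX41	c.679A>G	chr5	176939881	A	G	missense	0	1	0	1000	36	0.036
DDX41	c.679A>G	chr5	176939881	A	G	missense	0	2	42	1000	44	0.044
DDX41	c.679A>G	chr5	176939881	A	G	missense	0	3	142	1000	95	0.095
DDX41	c.679A>G	chr5	176939881	A	G	missense	0	4	364	1000	124	0.124
BAX	c.280C>T	chr19	49459151	C	T	nonsense	0	1	0	1000	84	0.084
BAX	c.280C>T	chr19	49459151	C	T	nonsense	0	2	42	1000	95	0.095
BAX	c.280C>T	chr19	49459151	C	T	nonsense	0	3	142	1000	80	0.080
BAX	c.280C>T	chr19	49459151	C	T	nonsense	0	4	364	1000	168	0.168
ATM	c.1262C>A	chr11	108121753	C	A	nonsense	0	1	0	1000	47	0.047
ATM	c.1262C>A	chr11	108121753	C	A	nonsense	0	2	42	1000	26	0.026
ATM	c.1262C>A	chr11	108121753	C	A	nonsense	0	3	142	1000	25	0.025
ATM	c.1262C>A	chr11	108121753	C	A	nonsense	0	4	364	NA	NA	NA
ZNF676	c.1564G>T	chr19	22361546	G	T	nonsense	0	1	0	1000	42	0.042
ZNF676	c.1564G>T	chr19	22361546	G	T	nonsense	0	2	42	NA	NA	NA
ZNF676	c.1564G>T	chr19	22361546	G	T	nonsense	0	3	142	NA	NA	NA
ZNF676	c.1564G>T	chr19	22361546	G	T	nonsense	0	4	364	NA	NA	NA
PRPF3	c.11C>A	chr1	150293925	C	A	nonsense	0	1	0	1000	12	0.012
PRPF3	c.11C>A	chr1	150293925	C	A	nonsense	0	2	42	NA	NA	NA
PRPF3	c.11C>A	chr1	150293925	C	A	nonsense	0	3	142	NA	NA	NA
PRPF3	c.11C>A	chr1	150293925	C	A	nonsense	0	4	364	NA	NA	NA
GPC3	c.352G>T	chrX	132948465	G	T	missense	0	1	0	1000	22	0.022
GPC3	c.352G>T	chrX	132948465	G	T	missense	0	2	42	NA	NA	NA
GPC3	c.352G>T	chrX	132948465	G	T	missense	0	3	142	NA	NA	NA
GPC3	c.352G>T	chrX	132948465	G	T	missense	0	4	364	1000	17	0.017
GPC3	c.355G>T	chrX	132948468	G	T	missense	0	1	0	1000	19	0.019
GPC3	c.355G>T	chrX	132948468	G	T	missense	0	2	42	NA	NA	NA
GPC3	c.355G>T	chrX	132948468	G	T	missense	0	3	142	NA	NA	NA
GPC3	c.355G>T	chrX	132948468	G	T	missense	0	4	364	NA	NA	NA
KMT2C	c.2576G>T	chr7	151891322	G	T	missense	0	1	0	1000	132	0.132
KMT2C	c.2576G>T	chr7	151891322	G	T	missense	0	2	42	NA	NA	NA
KMT2C	c.2576G>T	chr7	151891322	G	T	missense	0	3	142	NA	NA	NA
KMT2C	c.2576G>T	chr7	151891322	G	T	missense	0	4	364	NA	NA	NA
KDR	c.409T>G	chr4	55980456	T	G	missense	0	1	0	1000	22	0.022
KDR	c.409T>G	chr4	55980456	T	G	missense	0	2	42	NA	NA	NA
KDR	c.409T>G	chr4	55980456	T	G	missense	0	3	142	NA	NA	NA
KDR	c.409T>G	chr4	55980456	T	G	missense	0	4	364	NA	NA	NA
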