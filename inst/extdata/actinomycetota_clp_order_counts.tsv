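Order	ClpB	ClpC	ClpIa	ClpIb
Pseudonocardiales	83	73	25	7
Actinomycetales	36	39	0	1
Kineosporiales	7	6	0	0
Nakamurellales	4	4	0	0
Jiangellales	6	6	1	0
Micromonosporales	64	58	50	5
Bifidobacteriales	46	36	0	1
Cryptosporangiales	1	1	0	0
Actinopolysporales	2	2	2	0
Frankiales	23	16	1	0
Catenulisporales	2	1	0	1
Propionibacteriales	113	96	0	0
Mycobacteriales	204	185	15	14
Acidothermales	1	1	0	0
Streptosporangiales	75	50	18	14
Glycomycetales	3	3	0	0
Streptomycetales	296	230	117	78
Coriobacteriales	1	0	0	0
Geodermatophilales	22	21	9	1
Micrococcales	305	334	88	3
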