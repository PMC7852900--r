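region	class	n_denovo	denovo_maternal	denovo_paternal	denovo_unresolved	inherited_maternal	inherited_paternal	n_mosaic
1q21.1	deletion	2	0	2	0	3	1	0
1q21.1	duplication	0	0	0	0	4	0	0
3q29	deletion	1	0	1	0	0	0	0
3q29	duplication	0	0	0	0	0	0	0
7q11.23	deletion	0	0	0	0	0	0	0
7q11.23	duplication	0	0	0	0	0	0	0
15q11.2-13.1	deletion	0	0	0	0	0	0	0
15q11.2-13.1	duplication	2	2	0	0	1	0	1
15q13.3	deletion	1	0	1	0	3	1	0
15q13.3	duplication	1	0	1	0	2	3	0
16p11.2_distal	deletion	1	1	0	0	1	1	0
16p11.2_distal	duplication	2	1	0	1	1	5	0
16p11.2_proximal	deletion	4	3	1	0	2	0	0
16p11.2_proximal	duplication	0	0	0	0	4	1	0
17p13.3	deletion	0	0	0	0	0	0	0
17p13.3	duplication	0	0	0	0	0	0	0
17p11.2	deletion	0	0	0	0	0	0	0
17p11.2	duplication	0	0	0	0	0	0	0
17q12	deletion	3	1	2	0	0	0	0
17q12	duplication	0	0	0	0	1	1	0
17q21.31	deletion	0	0	0	0	0	0	0
17q21.31	duplication	0	0	0	0	0	0	0
22q11.2	deletion	1	1	0	0	0	0	0
22q11.2	duplication	2	1	1	0	2	2	0
22q11.2_distal	deletion	0	0	0	0	0	0	0
22q11.2_distal	duplication	0	0	0	0	0	0	0
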