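position	refColumn	phase
1	18	0
2	46	1
3	101	2
4	144	0
5	216	0
6	271	1
7	332	2
8	378	0
9	451	1
10	495	0
11	602	2
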