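taxid	parent	rank
1	1	no rank
2	1	superkingdom
3	1	domain
4	2	phylum
5	2	phylum
6	4	class
7	5	class
8	6	order
9	7	order
10	8	family
11	8	family
12	9	family
13	10	genus
14	10	genus
15	11	genus
16	12	genus
17	13	species
18	13	species
19	14	species
20	15	species
21	16	species
22	17	subspecies
23	17	no rank
24	3	phylum
25	24	order
26	25	family
27	26	genus
28	27	species
29	2	no rank
30	29	phylum
31	30	class
32	31	order
33	32	family
34	33	genus
35	34	species
36	35	subspecies
37	21	strain
38	13	species
39	14	species
40	19	subspecies
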