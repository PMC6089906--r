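taxid	name	class
1	root	scientific name
2	Bacteriomorpha	scientific name
3	Archaeomorpha	scientific name
4	Alphaphyla	scientific name
5	Betaphyla	scientific name
6	Alphaclassia	scientific name
7	Betaclassia	scientific name
8	Alphaordines	scientific name
9	Betaordines	scientific name
10	Familia_prima	scientific name
11	Familia_secunda	scientific name
12	Familia_tertia	scientific name
13	Genusunum	scientific name
14	Genusduo	scientific name
15	Genustria	scientific name
16	Genusquattuor	scientific name
17	g1_species1	scientific name
18	g1_species2	scientific name
19	g2_species1	scientific name
20	g3_species1	scientific name
21	g4_species1	scientific name
22	g1_species1_ssp1	scientific name
23	g1_species1_strainX	scientific name
24	Gammaphyla	scientific name
25	Gammaordines	scientific name
26	Familia_quarta	scientific name
27	Genusquinque	scientific name
28	ag1_species1	scientific name
29	environmental_clade	scientific name
30	Deltaphyla	scientific name
31	Deltaclassia	scientific name
32	Deltaordines	scientific name
33	Familia_quinta	scientific name
34	Genussex	scientific name
35	g5_species1	scientific name
36	g5_species1_ssp1	scientific name
37	g4_species1_strain1	scientific name
38	shared_species_name	scientific name
39	shared_species_name	scientific name
40	g2_species1_ssp1	scientific name
17	g1 sp. one	synonym
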