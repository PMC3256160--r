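column	category	groups	label	subtype	code_Archaea	code_Bacteria	code_Eukaryota	coord_Ecoli	coord_Scer	functions
1	UNIVERSAL		UNIVERSAL	NA	A	A	A	A354	A412	NONE
2	PAIR	Archaea,Eukaryota	PAIR(Archaea+Eukaryota)	INDEL	-	H	-	A355	(A412)-(T413)	NONE
3	UNIVERSAL		UNIVERSAL	NA	T	T	T	T356	T413	NONE
4	UNIVERSAL		UNIVERSAL	NA	G	G	G	G357	G414	NONE
5	PAIR	Archaea,Eukaryota	PAIR(Archaea+Eukaryota)	SUBSTITUTION	G	Y	G	T358	G415	A_SITE
6	UNIVERSAL		UNIVERSAL	NA	C	C	C	C359	C416	NONE
7	UNIVERSAL		UNIVERSAL	NA	G	G	G	G360	G417	NONE
8	PAIR	Archaea,Eukaryota	PAIR(Archaea+Eukaryota)	SUBSTITUTION	G	C	D	C361	A418	ANTIBIOTIC_RESISTANCE,PTC
9	UNIVERSAL		UNIVERSAL	NA	A	A	A	A362	A419	NONE
10	UNIVERSAL		UNIVERSAL	NA	G	G	G	G363	G420	NONE
11	PAIR	Archaea,Eukaryota	PAIR(Archaea+Eukaryota)	SUBSTITUTION	B	-	H	(G363)-(C364)	A421	NONE
12	PAIR	Archaea,Eukaryota	PAIR(Archaea+Eukaryota)	SUBSTITUTION	G	Y	R	C364	A422	NONE
13	UNIVERSAL		UNIVERSAL	NA	T	T	T	T365	T423	NONE
14	UNIVERSAL		UNIVERSAL	NA	C	C	C	C366	C424	NONE
15	PAIR	Archaea,Bacteria	PAIR(Archaea+Bacteria)	INDEL	-	-	N	(C366)-(G367)	A425	NONE
16	UNIVERSAL		UNIVERSAL	NA	G	G	G	G367	G426	NONE
17	UNIVERSAL		UNIVERSAL	NA	A	A	A	A368	A427	NONE
18	ONLY	Eukaryota	ONLY(Eukaryota)	SUBSTITUTION	-T	M	G	A369	G428	NONE
19	UNIVERSAL		UNIVERSAL	NA	C	C	C	C370	C429	NONE
20	UNIVERSAL		UNIVERSAL	NA	T	T	T	T371	T430	NONE
21	ONLY	Archaea	ONLY(Archaea)	INDEL	-	R	Y	A372	C431	NONE
22	UNIVERSAL		UNIVERSAL	NA	G	G	G	G373	G432	NONE
23	UNIVERSAL		UNIVERSAL	NA	A	A	A	A374	A433	NONE
25	UNIVERSAL		UNIVERSAL	NA	C	C	C	C376	C435	NONE
26	UNIVERSAL		UNIVERSAL	NA	G	G	G	G377	G436	NONE
28	UNIVERSAL		UNIVERSAL	NA	T	T	T	T379	T438	NONE
29	UNIVERSAL		UNIVERSAL	NA	A	A	A	A380	A439	NONE
32	UNIVERSAL		UNIVERSAL	NA	C	C	C	C383	C442	NONE
33	UNIVERSAL		UNIVERSAL	NA	G	G	G	G384	G443	NONE
34	UNIVERSAL		UNIVERSAL	NA	T	T	T	T385	T444	NONE
36	UNIVERSAL		UNIVERSAL	NA	A	A	A	A387	A446	NONE
37	UNIVERSAL		UNIVERSAL	NA	G	G	G	G388	G447	NONE
38	UNIVERSAL		UNIVERSAL	NA	C	C	C	C389	C448	NONE
39	UNIVERSAL		UNIVERSAL	NA	T	T	T	T390	T449	NONE
40	UNIVERSAL		UNIVERSAL	NA	G	G	G	G391	G450	NONE
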