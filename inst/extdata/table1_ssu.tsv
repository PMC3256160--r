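# Published SSU (16S-18S) rDNA signature rows, transcribed: per-group
# consensus codes with E. coli / S. cerevisiae reference coordinates.
# sharing: A = Archaea, E = Eukaryota, B = Bacteria.
sharing	Bacteria	Ecoli_site	Archaea	Eukaryota	Scer_site
A, E	H	T340	-	-	(A412)-(T413)
A, E	Y	T358	G	G	G430
A, E	C	C507	G	D	G553
A, E	-Y	-C514	BG	HR	G561
A, E	R	G537	C	Y	C584
A, E	R	G585	C	Y	T632
A, E	A	A716	C	B	C927
A, E	Y	C756	G	R	A967
A, E	G	G966	T	Y	T1191
A, E	A	A1110	G	G	G1330
B, A	-	(C1203)-(A1204)	(Y)-(A)	N	G1435
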