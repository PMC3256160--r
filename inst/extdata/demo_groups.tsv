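Ecoli	Bacteria
Bsub	Bacteria
Tmar	Bacteria
Paer	Bacteria
Syne	Bacteria
Aful	Archaea
Mjan	Archaea
Ssol	Archaea
Scer	Eukaryota
Hsap	Eukaryota
Atha	Eukaryota
Ddis	Eukaryota
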