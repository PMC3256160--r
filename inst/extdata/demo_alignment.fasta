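>Ecoli demo bacterial reference (16S-like numbering via offset 353)
AATGTCGCAG-CTC-GAACTAGAACGGTACACGTAAGCTG
>Bsub
ACTGCCGCAG-TTC-GACCTGGAGCGGTACCCGTCAGCTG
>Tmar
ATTGCCGCAG-CTC-GAACTAGAACGGTACGCGTAAGCTG
>Paer
AATGTCGCAG-TTC-GACCTGGAGCGGTACTCGTCAGCTG
>Syne
ACTGCCGCAG-CTC-GAACTAGAACGGTACACGTAAGCTG
>Aful
A-TGGCGGAGCGTC-GATCT-GAACGNTATACGTAAGCTG
>Mjan
A-TGGCGGAGGGTC-GA-CT-GAACGNTATCCGTCAGCTG
>Ssol
A-TGGCGGAGTGTC-GATCT-GAACGNTATGCGTCAGCTG
>Scer demo eukaryotic reference (18S-like numbering via offset 411)
A-TGGCGAAGAATCAGAGCTCGAGCGGTATACGTAAGCTG
>Hsap
A-TGGCGGAGCGTCCGAGCTTGATCGGTATCCGTCAGCTG
>Atha
A-TGGCGTAGTATCGGAGCTCGAGCGGTATGCGTAAGCTG
>Ddis
A-TGGCGGAGCGTCTGAGCTTGATCGGTATTCGTCAGCTG
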