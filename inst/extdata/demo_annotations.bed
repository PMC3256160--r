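# synthetic demo functional annotation in Ecoli published numbering
# (0-based half-open over published positions); illustrative only
Ecoli	357	358	A_SITE
Ecoli	360	361	PTC,ANTIBIOTIC_RESISTANCE
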