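# demo variable-length region, alignment columns, 0-based half-open
variable_region_1	29	31
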