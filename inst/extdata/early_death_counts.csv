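genotype,count
WT,9
het,18
KO,19
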