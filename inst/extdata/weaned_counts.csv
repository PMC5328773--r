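category,count
mWT,102
fWT,88
mhet,168
fhet,145
mKO,59
fKO,62
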