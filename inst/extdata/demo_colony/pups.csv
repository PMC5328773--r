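pup_id,litter_id,sex,genotype,death_day,weaned
P0001,L001,M,WT,,TRUE
P0002,L001,M,het,,TRUE
P0003,L001,F,het,,TRUE
P0004,L001,F,WT,,TRUE
P0005,L001,M,KO,14,FALSE
P0006,L001,F,KO,,TRUE
P0007,L001,M,het,,TRUE
P0008,L001,F,het,,TRUE
P0009,L002,F,WT,,TRUE
P0010,L002,M,het,,TRUE
P0011,L002,M,het,,TRUE
P0012,L002,F,KO,13,FALSE
P0013,L002,M,WT,,TRUE
P0014,L002,F,het,,TRUE
P0015,L002,M,KO,,TRUE
P0016,L002,F,het,1,FALSE
P0017,L002,M,,1,FALSE
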