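litter_id,dam_id,parity,birth_date,period,complete
L001,D001,1,2013-04-02,construction,TRUE
L002,D002,2,2014-11-20,quiescent,FALSE
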