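set,category,count
all,mWT,107
all,fWT,93
all,mhet,182
all,fhet,164
all,mKO,80
all,fKO,90
quiescent_complete,mWT,23
quiescent_complete,fWT,18
quiescent_complete,mhet,44
quiescent_complete,fhet,39
quiescent_complete,mKO,19
quiescent_complete,fKO,13
construction_complete,mWT,25
construction_complete,fWT,15
construction_complete,mhet,40
construction_complete,fhet,20
construction_complete,mKO,13
construction_complete,fKO,24
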