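category,weight_g,lean_p,fat_p,total_water_p,free_water_p
mWT,22.0,0.859,0.074,0.739,0.007
mhet,22.9,0.857,0.076,0.737,0.005
mKO,17.5,0.838,0.095,0.727,0.005
fWT,18.4,0.821,0.097,0.722,0.006
fhet,18.5,0.825,0.092,0.732,0.006
fKO,15.5,0.808,0.121,0.709,0.006
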