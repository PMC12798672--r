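label,min_m,max_m
Terrestrial,0,0
Intertidal,0,30
Shallow,30,200
Upper bathyal,200,1000
Deep sea,1000,Inf
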