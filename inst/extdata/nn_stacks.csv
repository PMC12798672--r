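pair1,pair2,dG37,dH
AU,AU,-0.93,-6.82
UA,UA,-0.93,-6.82
AU,UA,-1.10,-9.38
UA,AU,-1.33,-7.69
CG,UA,-2.08,-10.48
AU,GC,-2.08,-10.48
CG,AU,-2.11,-10.44
UA,GC,-2.11,-10.44
GC,UA,-2.24,-11.40
AU,CG,-2.24,-11.40
GC,AU,-2.35,-12.44
UA,CG,-2.35,-12.44
CG,GC,-2.36,-10.64
GC,GC,-3.26,-13.39
CG,CG,-3.26,-13.39
GC,CG,-3.42,-14.88
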