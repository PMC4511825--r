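trait_a,trait_b,r
SD,TD,0.74
SD,LMA,-0.75
SD,VD,0.32
SD,VDi,-0.29
TD,LMA,-0.76
TD,VD,0.41
TD,VDi,-0.46
LMA,VD,-0.75
LMA,VDi,0.63
VD,VDi,-0.73
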