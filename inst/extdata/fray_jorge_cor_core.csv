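trait_a,trait_b,r
SD,TD,0.34
SD,LMA,-0.87
SD,VD,0.04
SD,VDi,0.01
TD,LMA,-0.25
TD,VD,0.04
TD,VDi,0.05
LMA,VD,-0.18
LMA,VDi,0.06
VD,VDi,-0.90
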