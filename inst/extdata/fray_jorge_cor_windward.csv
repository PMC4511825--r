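trait_a,trait_b,r
SD,TD,0.55
SD,LMA,-0.03
SD,VD,-0.56
SD,VDi,0.16
TD,LMA,-0.22
TD,VD,-0.76
TD,VDi,0.11
LMA,VD,0.00
LMA,VDi,-0.27
VD,VDi,-0.16
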