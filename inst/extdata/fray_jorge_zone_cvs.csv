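zone,trait,cv
windward,SD,0.05
windward,TD,0.20
windward,LMA,0.30
windward,VD,0.12
windward,VDi,0.06
windward,Ks,0.28
windward,SM,0.30
windward,psi_PD,0.35
windward,psi_MD,0.25
core,SD,0.11
core,TD,0.16
core,LMA,0.34
core,VD,0.12
core,VDi,0.09
core,Ks,0.27
core,SM,0.30
core,psi_PD,0.35
core,psi_MD,0.25
leeward,SD,0.21
leeward,TD,0.29
leeward,LMA,0.27
leeward,VD,0.12
leeward,VDi,0.07
leeward,Ks,0.72
leeward,SM,0.30
leeward,psi_PD,0.35
leeward,psi_MD,0.25
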