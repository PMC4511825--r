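size_class,zone,trait,mean
large,windward,SM,9.25
large,windward,psi_PD,0.145
large,windward,psi_MD,0.725
large,windward,SD,108
large,windward,TD,4.7
large,windward,LMA,150.5
large,windward,VD,285
large,windward,VDi,17.95
large,windward,Ks,0.41
large,core,SM,14.6
large,core,psi_PD,0.10
large,core,psi_MD,0.71
large,core,SD,123
large,core,TD,5.0
large,core,LMA,139
large,core,VD,302
large,core,VDi,16.7
large,core,Ks,0.365
large,leeward,SM,4.7
large,leeward,psi_PD,0.825
large,leeward,psi_MD,1.71
large,leeward,SD,170.5
large,leeward,TD,10.7
large,leeward,LMA,273
large,leeward,VD,309.5
large,leeward,VDi,16.9
large,leeward,Ks,0.10
small,windward,SM,10.45
small,windward,psi_PD,0.545
small,windward,psi_MD,1.265
small,windward,SD,143.5
small,windward,TD,9.3
small,windward,LMA,203.5
small,windward,VD,330.5
small,windward,VDi,16.65
small,windward,Ks,0.39
small,core,SM,12.1
small,core,psi_PD,0.565
small,core,psi_MD,1.415
small,core,SD,130
small,core,TD,6.5
small,core,LMA,173.5
small,core,VD,330.5
small,core,VDi,16.65
small,core,Ks,0.24
small,leeward,SM,5.0
small,leeward,psi_PD,0.745
small,leeward,psi_MD,1.825
small,leeward,SD,147
small,leeward,TD,9.5
small,leeward,LMA,210.5
small,leeward,VD,290.5
small,leeward,VDi,17.65
small,leeward,Ks,0.135
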