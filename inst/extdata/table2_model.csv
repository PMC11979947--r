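tissue,observable,value
HepM,CoA,1.1
HepM,Pyr,0.23
HepM,AcCoA,0.003
HepM,Cit,0.11
HepM,Iso,0.13
HepM,OXO,0.1
HepM,SCoA,0.8
HepM,Suc,0.5
HepM,Fum,0.42
HepM,Mal,1.41
HepM,OAA,0.07
HepM,NAD,5.2
HepM,NADH,0.02
HepM,NADP,0.33
HepM,NADPH,1.37
HepM,GSH,3.2
HepM,GSSG,0.39
HepM,kc_flux,65.5
RLM,CoA,0.74
RLM,Pyr,1.2
RLM,AcCoA,0.003
RLM,Cit,0.2
RLM,Iso,0.4
RLM,OXO,0.11
RLM,SCoA,0.85
RLM,Suc,0.74
RLM,Fum,1.2
RLM,Mal,2.9
RLM,OAA,0.56
RLM,NAD,4.8
RLM,NADH,0.4
RLM,NADP,0.29
RLM,NADPH,1.4
RLM,GSH,5.3
RLM,GSSG,0.18
RLM,kc_flux,45.2
RHM,CoA,0.73
RHM,Pyr,0.15
RHM,AcCoA,0.005
RHM,Cit,0.26
RHM,Iso,0.013
RHM,OXO,0.015
RHM,SCoA,1.2
RHM,Suc,0.67
RHM,Fum,0.33
RHM,Mal,0.36
RHM,OAA,0.063
RHM,NAD,5.1
RHM,NADH,0.025
RHM,NADP,0.04
RHM,NADPH,1.65
RHM,GSH,3.9
RHM,GSSG,0.49
RHM,kc_flux,153.4
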