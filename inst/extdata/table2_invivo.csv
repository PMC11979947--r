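tissue,observable,mean,sd,n,lo,hi,type
HepM,CoA,NA,NA,NA,0.27,2.4,interval
HepM,Pyr,0.21,0.17,5,NA,NA,point
HepM,AcCoA,NA,NA,NA,0.1,0.86,interval
HepM,Cit,0.06,0.03,3,NA,NA,point
HepM,Iso,0.07,0.05,4,NA,NA,point
HepM,OXO,0.5,0.4,3,NA,NA,point
HepM,SCoA,0.5,0.05,3,NA,NA,point
HepM,Suc,0.9,0.16,3,NA,NA,point
HepM,Fum,0.31,0.1,3,NA,NA,point
HepM,Mal,1.35,0.26,3,NA,NA,point
HepM,OAA,0.1,0.09,5,NA,NA,point
HepM,NAD,NA,NA,NA,4,6.4,interval
HepM,NADH,NA,NA,NA,0.1,0.3,interval
HepM,NADP,NA,NA,NA,0.5,1.35,interval
HepM,NADPH,NA,NA,NA,0.2,1.2,interval
HepM,GSH,NA,NA,NA,1.6,5,interval
HepM,GSSG,NA,NA,NA,0.3,0.4,interval
HepM,kc_flux,66,1,4,NA,NA,flux
RLM,CoA,NA,NA,NA,0.27,2.4,interval
RLM,Pyr,1,0.6,4,NA,NA,point
RLM,AcCoA,NA,NA,NA,0.1,0.86,interval
RLM,Cit,3,1.8,5,NA,NA,point
RLM,Iso,0.15,0.08,5,NA,NA,point
RLM,OXO,0.18,0.17,4,NA,NA,point
RLM,SCoA,0.2,0.2,4,NA,NA,point
RLM,Suc,0.63,0.37,4,NA,NA,point
RLM,Fum,0.18,0.02,3,NA,NA,point
RLM,Mal,2,0.71,3,NA,NA,point
RLM,OAA,0.2,0.11,4,NA,NA,point
RLM,NAD,NA,NA,NA,4,6.4,interval
RLM,NADH,NA,NA,NA,0.1,0.3,interval
RLM,NADP,NA,NA,NA,0.5,1.35,interval
RLM,NADPH,NA,NA,NA,0.5,1.35,interval
RLM,GSH,NA,NA,NA,2.8,7.4,interval
RLM,GSSG,NA,NA,NA,0.1,0.5,interval
RLM,kc_flux,45,3,4,NA,NA,flux
RHM,CoA,NA,NA,NA,0.27,2.4,interval
RHM,Pyr,0.16,0.11,6,NA,NA,point
RHM,AcCoA,NA,NA,NA,0.1,0.86,interval
RHM,Cit,0.8,0.8,6,NA,NA,point
RHM,Iso,0.31,0.02,5,NA,NA,point
RHM,OXO,0.05,0.004,3,NA,NA,point
RHM,SCoA,0.5,0.57,3,NA,NA,point
RHM,Suc,1.2,1,3,NA,NA,point
RHM,Fum,0.05,0.03,6,NA,NA,point
RHM,Mal,2,1,6,NA,NA,point
RHM,OAA,0.1,0.03,5,NA,NA,point
RHM,NAD,NA,NA,NA,4,6.4,interval
RHM,NADH,NA,NA,NA,0.1,0.3,interval
RHM,NADP,NA,NA,NA,0.5,1.35,interval
RHM,NADPH,NA,NA,NA,0.5,1.35,interval
RHM,GSH,NA,NA,NA,3.4,5,interval
RHM,GSSG,NA,NA,NA,0.15,0.55,interval
RHM,kc_flux,152,4,4,NA,NA,flux
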