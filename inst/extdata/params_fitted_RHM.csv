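enzyme_id,mechanism,name,value,units,provenance
PT,uni_uni,Vmaxf,251.682990576557,nmol/min/mg,CALIBRATED
SCS,ter_ter,Vmaxf,8536.95957545698,nmol/min/mg,CALIBRATED
MAL_SUC,bi_bi,Vmaxf,21.4055474761183,nmol/min/mg,CALIBRATED
MAL_ISO,bi_bi,Vmaxf,3510.87656947903,nmol/min/mg,CALIBRATED
MAL_OXO,bi_bi,Vmaxf,1.21006926971265,nmol/min/mg,CALIBRATED
NADH_CONS,constant_flux,Vc,161.733295630608,nmol/min/mg,CALIBRATED
GSH_OX,constant_flux,Vc,0.974720857554484,nmol/min/mg,CALIBRATED
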