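enzyme_id,mechanism,name,value,units,provenance
PT,uni_uni,Vmaxf,5.56421944313021,nmol/min/mg,CALIBRATED
SCS,ter_ter,Vmaxf,20000,nmol/min/mg,CALIBRATED
MAL_SUC,bi_bi,Vmaxf,21.7248500524189,nmol/min/mg,CALIBRATED
MAL_ISO,bi_bi,Vmaxf,419.454201172874,nmol/min/mg,CALIBRATED
MAL_OXO,bi_bi,Vmaxf,5000,nmol/min/mg,CALIBRATED
NADH_CONS,constant_flux,Vc,93.2935192231676,nmol/min/mg,CALIBRATED
GSH_OX,constant_flux,Vc,42.1505021414184,nmol/min/mg,CALIBRATED
ACO,uni_uni,Vmaxf,31,nmol/min/mg,CALIBRATED
GDH,gdh_mwc,activity,20,nmol/min/mg,CALIBRATED
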