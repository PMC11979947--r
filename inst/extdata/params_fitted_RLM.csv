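enzyme_id,mechanism,name,value,units,provenance
PT,uni_uni,Vmaxf,25.2177218349873,nmol/min/mg,CALIBRATED
SCS,ter_ter,Vmaxf,3693.01710495209,nmol/min/mg,CALIBRATED
MAL_SUC,bi_bi,Vmaxf,32.6049667794485,nmol/min/mg,CALIBRATED
MAL_ISO,bi_bi,Vmaxf,572.197618093187,nmol/min/mg,CALIBRATED
NADH_CONS,constant_flux,Vc,96.6891031872015,nmol/min/mg,CALIBRATED
GSH_OX,constant_flux,Vc,6.23883182147391,nmol/min/mg,CALIBRATED
ACO,uni_uni,Vmaxf,20.3810792253083,nmol/min/mg,CALIBRATED
IDH_NAD,mwc_idh,Vmaxf,9.50890158806218,nmol/min/mg,CALIBRATED
PDH,ter_bi,Vmaxf,21.3498671070364,nmol/min/mg,CALIBRATED
OGDH,ter_bi,Vmaxf,60,nmol/min/mg,CALIBRATED
GDH,gdh_mwc,activity,1.44211585471626,nmol/min/mg,CALIBRATED
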