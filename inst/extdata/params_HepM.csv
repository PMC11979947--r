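enzyme_id,mechanism,name,value,units,provenance
PT,uni_uni,Ka,0.3,mM,ASSUMED
PT,uni_uni,Kp,0.3,mM,ASSUMED
PT,uni_uni,Keq,1,dimensionless,ASSUMED
PDH,ter_bi,Kp,0.05,mM,ASSUMED
PDH,ter_bi,Kq,0.05,mM,ASSUMED
PDH,ter_bi,Keq,1e+08,mM,ASSUMED
PDH,ter_bi,co2_folded,1,dimensionless,PAPER-2.6
CS,random_bi_bi,Kp,0.05,mM,ASSUMED
CS,random_bi_bi,Kq,1.6,mM,ASSUMED
CS,random_bi_bi,Keq,2200000,dimensionless,ASSUMED
ACO,uni_uni,Kp,0.6,mM,ASSUMED
ACO,uni_uni,Keq,2,dimensionless,ASSUMED
IDH_NAD,mwc_idh,Kp,1,mM,ASSUMED
IDH_NAD,mwc_idh,Kq,0.05,mM,ASSUMED
IDH_NAD,mwc_idh,Keq,25000,mM,ASSUMED
IDH_NAD,mwc_idh,co2_folded,1,dimensionless,PAPER-2.6
IDH_NADP,bi_bi_inhib,Kp,2,mM,ASSUMED
IDH_NADP,bi_bi_inhib,Kq,0.036,mM,ASSUMED
IDH_NADP,bi_bi_inhib,Ki_GSH,3,mM,ASSUMED
IDH_NADP,bi_bi_inhib,Ki_NAD,0.6,mM,ASSUMED
IDH_NADP,bi_bi_inhib,Keq,25000,mM,ASSUMED
IDH_NADP,bi_bi_inhib,co2_folded,1,dimensionless,PAPER-2.6
OGDH,ter_bi,Kp,0.6,mM,ASSUMED
OGDH,ter_bi,Kq,0.05,mM,ASSUMED
OGDH,ter_bi,Keq,1e+08,mM,ASSUMED
OGDH,ter_bi,co2_folded,1,dimensionless,PAPER-2.6
SCS,ter_ter,Ka,0.041,mM,ASSUMED
SCS,ter_ter,Kb,0.25,mM,ASSUMED
SCS,ter_ter,Kc,0.72,mM,ASSUMED
SCS,ter_ter,Kp,0.45,mM,ASSUMED
SCS,ter_ter,Kq,0.3,mM,ASSUMED
SCS,ter_ter,Kr,2,mM,ASSUMED
SCS,ter_ter,Keq,3.7,dimensionless,ASSUMED
SDH,bi_bi,Kb,0.12,mM,ASSUMED
SDH,bi_bi,Kp,0.15,mM,ASSUMED
SDH,bi_bi,Kq,0.9,mM,ASSUMED
SDH,bi_bi,Keq,3.2,dimensionless,ASSUMED
AST,bi_bi,Kp,0.1,mM,ASSUMED
AST,bi_bi,Kq,4,mM,ASSUMED
AST,bi_bi,Keq,0.15,dimensionless,ASSUMED
ALT,bi_bi,Kp,0.3,mM,ASSUMED
ALT,bi_bi,Kq,6,mM,ASSUMED
ALT,bi_bi,Keq,1,dimensionless,ASSUMED
ME,bi_bi,Kp,3,mM,ASSUMED
ME,bi_bi,Kq,0.03,mM,ASSUMED
ME,bi_bi,Keq,34,mM,ASSUMED
GDH,gdh_mwc,Ka,0.53,mM,PAPER-Table1
GDH,gdh_mwc,Kb,8.8,mM,PAPER-Table1
GDH,gdh_mwc,Vmaxr,19,nmol/min/mg,PAPER-Table1
GDH,gdh_mwc,Kp,0.08,mM,PAPER-Table1
GDH,gdh_mwc,Kq,0.025,mM,ASSUMED
GDH,gdh_mwc,Kr,1.1,mM,ASSUMED
GDH,gdh_mwc,L,2,dimensionless,ASSUMED
GDH,gdh_mwc,n,4,dimensionless,ASSUMED
GDH,gdh_mwc,Ka_ADP,1,mM,ASSUMED
GDH,gdh_mwc,Ki_GTP,0.5,mM,ASSUMED
GR,gr_bi_ter,Vmaxf,60,nmol/min/mg,ASSUMED
GR,gr_bi_ter,Ka,0.01,mM,ASSUMED
GR,gr_bi_ter,Kb,0.06,mM,ASSUMED
GR,gr_bi_ter,Kp,0.1,mM,ASSUMED
GR,gr_bi_ter,Kq,10,mM,ASSUMED
GR,gr_bi_ter,Kr,10,mM,ASSUMED
GR,gr_bi_ter,Keq,50000,mM,ASSUMED
MAL_SUC,bi_bi,Ka,0.5,mM,ASSUMED
MAL_SUC,bi_bi,Kb,1,mM,ASSUMED
MAL_SUC,bi_bi,Kp,0.5,mM,ASSUMED
MAL_SUC,bi_bi,Kq,1,mM,ASSUMED
MAL_SUC,bi_bi,Keq,1,dimensionless,ASSUMED
MAL_ISO,bi_bi,Ka,0.5,mM,ASSUMED
MAL_ISO,bi_bi,Kb,0.2,mM,ASSUMED
MAL_ISO,bi_bi,Kp,0.5,mM,ASSUMED
MAL_ISO,bi_bi,Kq,0.2,mM,ASSUMED
MAL_ISO,bi_bi,Keq,1,dimensionless,ASSUMED
MAL_OXO,bi_bi,Ka,0.5,mM,ASSUMED
MAL_OXO,bi_bi,Kb,0.2,mM,ASSUMED
MAL_OXO,bi_bi,Kp,0.5,mM,ASSUMED
MAL_OXO,bi_bi,Kq,0.2,mM,ASSUMED
MAL_OXO,bi_bi,Keq,1,dimensionless,ASSUMED
CS,random_bi_bi,Vmaxf,1260,nmol/min/mg,PAPER-Table1
CS,random_bi_bi,Ka,0.003,mM,PAPER-Table1
CS,random_bi_bi,Kb,0.011,mM,PAPER-Table1
ACO,uni_uni,Vmaxf,23,nmol/min/mg,PAPER-Table1
ACO,uni_uni,Ka,0.26,mM,PAPER-Table1
IDH_NAD,mwc_idh,Vmaxf,51,nmol/min/mg,PAPER-Table1
IDH_NAD,mwc_idh,Kb,5.7,mM,PAPER-Table1
IDH_NAD,mwc_idh,Ki_NADH_vs_Iso,0.04,mM,PAPER-Table1
IDH_NAD,mwc_idh,n,2.33,dimensionless,PAPER-Table1
IDH_NAD,mwc_idh,L,0.64,dimensionless,PAPER-Table1
IDH_NAD,mwc_idh,Ka,0.25,mM,PAPER-Table1
IDH_NAD,mwc_idh,Ki_NADH_vs_NAD,0.08,mM,PAPER-Table1
OGDH,ter_bi,Vmaxf,22,nmol/min/mg,PAPER-Table1
OGDH,ter_bi,Ka,1,mM,PAPER-Table1
OGDH,ter_bi,Kb,0.015,mM,PAPER-Table1
OGDH,ter_bi,Kc,0.4,mM,PAPER-Table1
SDH,bi_bi,Vmaxf,13,nmol/min/mg,PAPER-Table1
SDH,bi_bi,Ka,0.07,mM,PAPER-Table1
FH,uni_uni_2V,Vmaxf,3356,nmol/min/mg,PAPER-Table1
FH,uni_uni_2V,Ka,1,mM,PAPER-Table1
FH,uni_uni_2V,Vmaxr,340,nmol/min/mg,PAPER-Table1
FH,uni_uni_2V,Kp,0.4,mM,PAPER-Table1
MDH,bi_bi_2V,Vmaxf,269,nmol/min/mg,PAPER-Table1
MDH,bi_bi_2V,Kb,0.45,mM,PAPER-Table1
MDH,bi_bi_2V,Ka,0.11,mM,PAPER-Table1
MDH,bi_bi_2V,Vmaxr,2074,nmol/min/mg,PAPER-Table1
MDH,bi_bi_2V,Kp,0.007,mM,PAPER-Table1
MDH,bi_bi_2V,Kq,0.017,mM,PAPER-Table1
IDH_NADP,bi_bi_inhib,Vmaxf,587,nmol/min/mg,PAPER-Table1
IDH_NADP,bi_bi_inhib,Kb,0.046,mM,PAPER-Table1
IDH_NADP,bi_bi_inhib,Ka,0.078,mM,PAPER-Table1
PDH,ter_bi,Vmaxf,26,nmol/min/mg,PAPER-Table1
PDH,ter_bi,Ka,0.21,mM,PAPER-Table1
PDH,ter_bi,Kb,0.014,mM,PAPER-Table1
PDH,ter_bi,Kc,0.34,mM,PAPER-Table1
AST,bi_bi,Vmaxf,527,nmol/min/mg,PAPER-Table1
AST,bi_bi,Ka,0.6,mM,PAPER-Table1
AST,bi_bi,Kb,1.3,mM,PAPER-Table1
ME,bi_bi,Vmaxf,6.5,nmol/min/mg,PAPER-Table1
ME,bi_bi,Kb,1.1,mM,PAPER-Table1
ME,bi_bi,Ka,0.4,mM,PAPER-Table1
ALT,bi_bi,Vmaxf,327,nmol/min/mg,PAPER-Table1
ALT,bi_bi,Ka,10,mM,PAPER-Table1
ALT,bi_bi,Kb,2,mM,PAPER-Table1
GDH,gdh_mwc,Vmaxf,5,nmol/min/mg,ASSUMED
PT,uni_uni,Vmaxf,100,nmol/min/mg,FREE
SCS,ter_ter,Vmaxf,200,nmol/min/mg,FREE
MAL_SUC,bi_bi,Vmaxf,50,nmol/min/mg,FREE
MAL_ISO,bi_bi,Vmaxf,50,nmol/min/mg,FREE
MAL_OXO,bi_bi,Vmaxf,50,nmol/min/mg,FREE
NADH_CONS,constant_flux,Vc,150,nmol/min/mg,FREE
GSH_OX,constant_flux,Vc,5,nmol/min/mg,FREE
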