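{
  "fixed": {
    "Pyr_out": 2,
    "Mal_out": 5,
    "Suc_out": 0.1,
    "OXO_out": 0.1,
    "Iso_out": 0.1,
    "ADP": 0.3,
    "Pi": 5,
    "ATP": 3,
    "Asp": 6,
    "Glu": 5,
    "Ala": 2,
    "NH4": 0.5,
    "GTP": 0.05,
    "CoQ": 1,
    "QH2": 0.1,
    "CO2": 2.2
  },
  "fixed_provenance": {
    "Pyr_out": "PAPER-2.5",
    "Mal_out": "PAPER-2.5",
    "Pi": "PAPER-2.5",
    "ADP": "PAPER-2.5",
    "CO2": "PAPER-2.6",
    "other": "ASSUMED"
  },
  "initial": {
    "Pyr": 0.16,
    "AcCoA": 0.005,
    "Cit": 0.8,
    "Iso": 0.31,
    "OXO": 0.05,
    "SCoA": 0.5,
    "Suc": 1.2,
    "Fum": 0.05,
    "Mal": 2,
    "OAA": 0.1,
    "NADH": 0.025,
    "NADPH": 1.65,
    "GSSG": 0.49
  },
  "moiety_totals": {
    "NAD_pool": 5.125,
    "NADP_pool": 1.69,
    "GSH_pool": 4.88,
    "CoA_pool": 1.935
  }
}
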