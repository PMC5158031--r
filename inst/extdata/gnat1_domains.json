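{
  "protein": "GNAT1",
  "protein_length": 350,
  "sites": [
    {"name": "Gtbg_1_23",     "start": 1,   "end": 23},
    {"name": "NLS_21_52",     "start": 21,  "end": 52},
    {"name": "Mg_43",         "start": 43,  "end": 43},
    {"name": "Mg_177",        "start": 177, "end": 177},
    {"name": "GTP_36_43",     "start": 36,  "end": 43},
    {"name": "GTP_171_177",   "start": 171, "end": 177},
    {"name": "GTP_196_200",   "start": 196, "end": 200},
    {"name": "GTP_265_268",   "start": 265, "end": 268},
    {"name": "GTP_321_323",   "start": 321, "end": 323},
    {"name": "PDE6G_306_310", "start": 306, "end": 310},
    {"name": "RHO_311_328",   "start": 311, "end": 328},
    {"name": "RHO_340_350",   "start": 340, "end": 350}
  ]
}
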