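[
  {
    "id": "water_typical",
    "arr": "F-H-T-R",
    "note": "ar/R selectivity filter F-H-T-R, the configuration typical of efficient water-transporting plasma-membrane aquaporins"
  },
  {
    "id": "formamide",
    "arr": "H-I-G-R",
    "note": "ar/R selectivity filter H-I-G-R, experimentally associated with formamide transport in tonoplast aquaporins"
  },
  {
    "id": "boric_acid_nip5_like",
    "npa_lb": "NPS",
    "npa_le": "NPV",
    "arr": "A-I-G-R",
    "note": "NPS/NPV aqueous pore combined with the A-I-G-R ar/R filter, the AtNIP5;1-type boric acid transporter signature"
  }
]
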