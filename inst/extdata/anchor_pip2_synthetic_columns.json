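{
  "anchor_id": "PIP2_anchor_synthetic",
  "columns": {
    "NPA_LB1": 96,
    "NPA_LB2": 97,
    "NPA_LB3": 98,
    "NPA_LE1": 218,
    "NPA_LE2": 219,
    "NPA_LE3": 220,
    "H2": 75,
    "H5": 202,
    "LE1": 222,
    "LE2": 224,
    "P1": 143,
    "P2": 227,
    "P3": 230,
    "P4": 273,
    "P5": 275,
    "SDP1": 49,
    "SDP2": 53,
    "SDP3": 90,
    "SDP4": 103,
    "SDP5": 138,
    "SDP6": 147,
    "SDP7": 182,
    "SDP8": 233,
    "SDP9": 237
  }
}
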