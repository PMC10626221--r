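{
  "name": "classical",
  "parent": {
    "MPP": "HSC",
    "LMPP": "MPP",
    "CMP": "MPP",
    "MLP": "LMPP",
    "GMP": "LMPP",
    "MEP": "CMP",
    "PC": "MLP",
    "lymphocyte": "MLP",
    "MB": "GMP",
    "neutrophil": "GMP",
    "eosinophil": "GMP",
    "erythrocyte": "MEP",
    "megakaryocyte": "MEP"
  },
  "leaf_slots": {
    "PC": "PC",
    "lymphocyte": "lymphocyte",
    "MB": "MB",
    "neutrophil": "neutrophil",
    "eosinophil": "eosinophil",
    "erythrocyte": "erythrocyte",
    "megakaryocyte": "megakaryocyte",
    "other": "HSC"
  }
}
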