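{
  "thyroid_function": ["TG", "TPO", "SLC26A7", "ID4", "PAX8", "IYD", "ID3", "TSHR", "SLC26A4"],
  "M1": ["CCL5", "IL1A", "IL1B", "IL18", "CCR7", "CD40", "CD86", "HLA-DPB1", "HLA-DPA1"],
  "M2": ["CCL13", "CCL18", "CCL20", "CD68", "CD276", "CD209", "CD163", "CTSA", "CTSB", "CTSD", "FN1", "LYVE1", "MMP9", "MMP14", "MMP19", "MSR1", "MRC1"],
  "cytotoxicity": ["CST7", "GZMA", "GZMB", "IFNG", "NKG7", "PRF1", "GZMK", "GZMH", "CCL3"],
  "exhaustion": ["CTLA4", "HAVCR2", "LAG3", "PDCD1", "TIGIT"]
}
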