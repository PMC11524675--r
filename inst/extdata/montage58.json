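{
  "left":  ["Fp1", "AF3", "F7", "F5", "F3", "F1", "FT7", "FC5", "FC3", "FC1",
            "T7", "C5", "C3", "C1", "TP7", "CP5", "CP3", "CP1",
            "P7", "P5", "P3", "P1", "PO7", "PO3", "O1"],
  "right": ["Fp2", "AF4", "F8", "F6", "F4", "F2", "FT8", "FC6", "FC4", "FC2",
            "T8", "C6", "C4", "C2", "TP8", "CP6", "CP4", "CP2",
            "P8", "P6", "P4", "P2", "PO8", "PO4", "O2"],
  "midline": ["Fpz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz"],
  "asymmetry_pairs": [
    ["Fp1", "Fp2"], ["AF3", "AF4"], ["F7", "F8"], ["F5", "F6"], ["F3", "F4"],
    ["F1", "F2"], ["FT7", "FT8"], ["FC5", "FC6"], ["FC3", "FC4"], ["FC1", "FC2"],
    ["T7", "T8"], ["C5", "C6"], ["C3", "C4"], ["C1", "C2"], ["TP7", "TP8"],
    ["CP5", "CP6"], ["CP3", "CP4"], ["CP1", "CP2"], ["P7", "P8"], ["P5", "P6"],
    ["P3", "P4"], ["P1", "P2"], ["PO7", "PO8"], ["PO3", "PO4"], ["O1", "O2"],
    ["AF3", "Fp2"]
  ]
}
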