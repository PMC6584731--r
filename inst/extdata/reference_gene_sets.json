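{
  "ovarian_prognostic_genes": ["PTCH1", "TGFBR2", "CXCL14", "POSTN", "FAP", "NUAK1"],
  "breast_module_prototypes": ["ESR1", "ERBB2", "STAT1", "CASP3", "PLAU", "VEGF", "AURKA"]
}
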