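# Five-substitution engineered receptor preset: pocket and beta-sheet
# changes transferred from the more SB-sensitive homolog into the wild
# type receptor.
name: cspyl1_5m
substitutions:
  - {res_seq: 112, from: VAL, to: LEU}
  - {res_seq: 137, from: PHE, to: ILE}
  - {res_seq: 135, from: THR, to: LEU}
  - {res_seq: 153, from: THR, to: ILE}
  - {res_seq: 168, from: VAL, to: ALA}
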