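# Default pharmacophore sphere descriptors, anchored on the bound
# reference ligand and two pocket residues.
descriptors:
  - name: keto_O
    anchor: {type: atom, atoms: [O1]}
    radius_A: 1.5
    property: hba
  - name: carboxylate
    anchor: {type: centroid, atoms: [O3, O4]}
    radius_A: 2.8
    property: hba
  - name: methyl
    anchor: {type: atom, atoms: [C6]}
    radius_A: 1.4
    property: hydrophobic
  - name: pocket_centroid
    anchor: {type: centroid, residues: [90, 139]}
    radius_A: 3.5
    property: hydrophobic
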