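# Standard amino-acid residue names (plus HOH handled separately).
.ag_standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Hydrogen-bond capable protein atoms by residue template (heavy-atom
# names, PDB v3).  Backbone N is a donor (except PRO), backbone O an
# acceptor, for every residue.  PDB crystal structures usually lack
# hydrogens, so protein typing is template-based rather than graph-based.
.ag_res_donors <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG")

.ag_res_acceptors <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

# Side-chain heavy-atom names per residue (PDB v3 order), used by the
# synthetic-structure generators to build idealized toy residues.
.ag_res_sidechain <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2"))

.ag_atom_element_from_name <- function(name) {
  one <- substr(gsub("^[0-9]", "", name), 1, 1)
  one
}

# Protein-atom H-bond typing from residue templates.
# Returns data.frame(donor, acceptor) aligned to the atom table.
.ag_protein_hbond_typing <- function(atoms) {
  n <- nrow(atoms)
  donor <- rep(FALSE, n)
  acceptor <- rep(FALSE, n)
  std <- atoms$res_name %in% .ag_standard_residues
  donor[std & atoms$name == "N" & atoms$res_name != "PRO"] <- TRUE
  acceptor[std & atoms$name %in% c("O", "OXT")] <- TRUE
  for (k in which(std)) {
    rn <- atoms$res_name[k]
    if (atoms$name[k] %in% .ag_res_donors[[rn]]) donor[k] <- TRUE
    if (atoms$name[k] %in% .ag_res_acceptors[[rn]]) acceptor[k] <- TRUE
  }
  w <- atoms$is_water & atoms$element == "O"
  donor[w] <- TRUE
  acceptor[w] <- TRUE
  data.frame(donor = donor, acceptor = acceptor)
}
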