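#' Pharmacophoric atom typing rules
#'
#' The pipeline's typing convention, centralized so users can swap it:
#'
#' * donor: N or O bearing at least one hydrogen (explicit or implicit).
#' * acceptor: any O with non-positive formal charge; N with non-positive
#'   formal charge and fewer than 3 heavy neighbors, excluding amide-type
#'   N (a neighbor carbon double-bonded to O or S) and pyrrole/aniline-type
#'   N (bearing H with every heavy neighbor an sp2/aromatic carbon).
#' * hydrophobic: C or S whose heavy neighbors are all C or S.
#'
#' This is a documented Lipinski-adjacent convention, not a reconstruction
#' of any docking program's internal definitions.
#'
#' @return list of rule parameters (donor_elements, acceptor_o_max_charge,
#'   acceptor_n_max_heavy_deg, hydrophobic_elements).
#' @export
typing_rules <- function() {
  list(donor_elements = c("N", "O"),
       acceptor_o_max_charge = 0L,
       acceptor_n_max_heavy_deg = 2L,
       hydrophobic_elements = c("C", "S"))
}

#' Assign per-atom pharmacophoric properties
#'
#' Flags every heavy atom as hydrogen-bond acceptor, hydrogen-bond donor
#' and/or hydrophobic under the convention of [typing_rules()].  Hydrogen
#' atoms are never flagged.
#'
#' @param mol an `agmol` with a valence-consistent bond graph.
#' @param rules rule set, default [typing_rules()].
#' @return data.frame (class `agtyping`) with logical columns `is_hba`,
#'   `is_hbd`, `is_hydrophobic` and integer `n_h`, one row per atom.
#' @examples
#' benzene <- molecule(
#'   atoms = data.frame(element = "C", name = paste0("C", 1:6),
#'                      x = cos(2 * pi * (0:5) / 6) * 1.39,
#'                      y = sin(2 * pi * (0:5) / 6) * 1.39, z = 0),
#'   bonds = data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))
#' colSums(type_atoms(benzene)[, 1:3])
#' @export
type_atoms <- function(mol, rules = typing_rules()) {
  stopifnot(inherits(mol, "agmol"))
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  n <- length(el)
  nh <- total_h_counts(mol)
  nb <- .ag_neighbors(mol)
  heavy <- el != "H"
  # per-atom: does this atom carry a double/triple/aromatic bond?
  sp2ish <- logical(n)
  dbl_to_os <- logical(n)  # carbon double-bonded to O or S
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
      if (o >= 2) { sp2ish[i] <- TRUE; sp2ish[j] <- TRUE }
      if (o == 2) {
        if (el[i] == "C" && el[j] %in% c("O", "S")) dbl_to_os[i] <- TRUE
        if (el[j] == "C" && el[i] %in% c("O", "S")) dbl_to_os[j] <- TRUE
      }
    }
  }
  is_hbd <- heavy & el %in% rules$donor_elements & nh >= 1L
  is_hba <- logical(n)
  is_hydro <- logical(n)
  for (a in seq_len(n)) {
    if (!heavy[a]) next
    hn <- nb[[a]][heavy[nb[[a]]]]
    if (el[a] == "O" && chg[a] <= rules$acceptor_o_max_charge)
      is_hba[a] <- TRUE
    if (el[a] == "N" && chg[a] <= 0L &&
        length(hn) <= rules$acceptor_n_max_heavy_deg) {
      amide <- any(el[hn] == "C" & dbl_to_os[hn])
      pyrrolish <- nh[a] >= 1L && length(hn) > 0 &&
        all(el[hn] == "C" & sp2ish[hn])
      if (!amide && !pyrrolish) is_hba[a] <- TRUE
    }
    if (el[a] %in% rules$hydrophobic_elements &&
        (length(hn) == 0 || all(el[hn] %in% rules$hydrophobic_elements)))
      is_hydro[a] <- TRUE
  }
  structure(data.frame(is_hba = is_hba, is_hbd = is_hbd,
                       is_hydrophobic = is_hydro, n_h = nh),
            class = c("agtyping", "data.frame"))
}

#' Molecular weight
#'
#' Sum of IUPAC standard atomic masses over all atoms including implicit
#' hydrogens.
#'
#' @param mol an `agmol`.
#' @return weight in Dalton.
#' @export
molecular_weight <- function(mol) {
  .ag_check_elements(mol$atoms$element, mol$title)
  sum(.ag_atomic_mass[mol$atoms$element]) +
    sum(implicit_h_counts(mol)) * .ag_atomic_mass[["H"]]
}

#' Count hydrogen-bond donor heavy atoms
#'
#' Donors are counted per donor heavy atom, not per attached hydrogen.
#'
#' @param mol an `agmol`.
#' @param typing optional precomputed [type_atoms()] result.
#' @return integer count.
#' @export
count_hbd <- function(mol, typing = type_atoms(mol)) sum(typing$is_hbd)

#' Count hydrogen-bond acceptor heavy atoms
#' @inheritParams count_hbd
#' @return integer count.
#' @export
count_hba <- function(mol, typing = type_atoms(mol)) sum(typing$is_hba)
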