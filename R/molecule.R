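#' Construct a small molecule
#'
#' A molecule is an explicit heavy-atom (optionally with explicit hydrogens)
#' bond graph with 3D coordinates in the receptor frame.  Bond orders are
#' 1, 2, 3 or 4 (aromatic).  Implicit hydrogens are derived from a standard
#' valence model when needed (see [implicit_h_counts()]).
#'
#' @param atoms data.frame with columns `element` (symbol), `name` (atom
#'   label), `x`, `y`, `z` (Angstrom) and optionally `charge` (integer
#'   formal charge, default 0).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3, or 4 for aromatic).  May have zero rows.
#' @param title molecule name.
#' @param properties named character vector of SDF data-tag properties.
#' @return an object of class `agmol`.
#' @examples
#' m <- molecule(
#'   atoms = data.frame(element = c("C", "O"), name = c("C1", "O1"),
#'                      x = c(0, 1.43), y = 0, z = 0),
#'   bonds = data.frame(i = 1, j = 2, order = 1), title = "methanol")
#' molecular_weight(m)
#' @export
molecule <- function(atoms, bonds = NULL, title = "", properties = character()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  atoms <- data.frame(element = as.character(atoms$element),
                      name = as.character(atoms$name),
                      x = as.numeric(atoms$x), y = as.numeric(atoms$y),
                      z = as.numeric(atoms$z),
                      charge = as.integer(atoms$charge),
                      stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in molecule", call. = FALSE)
  .ag_check_elements(atoms$element, title)
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.numeric(bonds$order))
    n <- nrow(atoms)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond references atom index out of range", call. = FALSE)
    if (any(bonds$i == bonds$j)) stop("self-bond in molecule", call. = FALSE)
    if (!all(bonds$order %in% c(1, 2, 3, 4)))
      stop("bond order must be 1, 2, 3 or 4 (aromatic)", call. = FALSE)
  }
  structure(list(atoms = atoms, bonds = bonds, title = as.character(title),
                 properties = properties),
            class = "agmol")
}

#' @export
print.agmol <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms (%d heavy), %d bonds>\n",
              x$title, nrow(x$atoms), sum(x$atoms$element != "H"),
              nrow(x$bonds)))
  invisible(x)
}

#' Heavy-atom flags of a molecule
#' @param mol an `agmol`.
#' @return logical vector, TRUE where the atom is not hydrogen.
#' @export
is_heavy <- function(mol) mol$atoms$element != "H"

#' Coordinates of a molecule
#' @param mol an `agmol`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
mol_coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

# Per-atom sum of explicit bond orders; aromatic bonds count 1.5.
.ag_bond_order_sum <- function(mol) {
  n <- nrow(mol$atoms)
  s <- numeric(n)
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + ord[k]
      s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + ord[k]
    }
  }
  s
}

# Heavy-atom neighbor lists (indices into atoms).
.ag_neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Implicit hydrogen counts
#'
#' Number of implicit hydrogens on each atom under the standard valence
#' model: the smallest allowed valence of the element (adjusted by formal
#' charge for N+ and O-) that is not below the rounded-up bond-order sum,
#' minus that sum.  Explicit hydrogens in the graph reduce the implicit
#' count through their bond.  Aromatic bonds (order 4) contribute 1.5 and
#' the total is rounded up; molecules using aromatic bond orders should
#' carry explicit hydrogens on atoms where this convention is ambiguous
#' (e.g. pyrrole nitrogen).
#'
#' @param mol an `agmol`.
#' @return integer vector, zero for hydrogen atoms.
#' @export
implicit_h_counts <- function(mol) {
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  s <- ceiling(.ag_bond_order_sum(mol) - 1e-9)
  out <- integer(nrow(mol$atoms))
  for (a in seq_along(el)) {
    if (el[a] == "H") next
    val <- .ag_valences[[el[a]]]
    if (el[a] == "N" && chg[a] == 1L) val <- 4
    if (el[a] == "O" && chg[a] == -1L) val <- 1
    if (el[a] == "O" && chg[a] == 1L) val <- 3
    val <- val[val >= s[a]]
    out[a] <- if (length(val)) as.integer(min(val) - s[a]) else 0L
  }
  out
}

#' Total hydrogen count per atom (explicit + implicit)
#' @param mol an `agmol`.
#' @return integer vector over atoms.
#' @export
total_h_counts <- function(mol) {
  nh <- implicit_h_counts(mol)
  if (nrow(mol$bonds)) {
    hyd <- mol$atoms$element == "H"
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (hyd[j]) nh[i] <- nh[i] + 1L
      if (hyd[i]) nh[j] <- nh[j] + 1L
    }
  }
  nh
}

#' Construct a docked ligand pose
#'
#' Wraps a molecule whose coordinates are in the receptor frame together
#' with an optional externally produced docking score (e.g. a CHEMPLP
#' value carried in an SDF tag).
#'
#' @param mol an `agmol` with 3D coordinates in the receptor frame.
#' @param docking_score numeric scalar or `NA` when absent.
#' @return an object of class `agpose`.
#' @export
ligand_pose <- function(mol, docking_score = NA_real_) {
  stopifnot(inherits(mol, "agmol"))
  structure(list(molecule = mol, docking_score = as.numeric(docking_score)),
            class = "agpose")
}

#' @export
print.agpose <- function(x, ...) {
  cat(sprintf("<pose '%s': %d atoms, docking score %s>\n",
              x$molecule$title, nrow(x$molecule$atoms),
              ifelse(is.na(x$docking_score), "absent",
                     format(x$docking_score))))
  invisible(x)
}
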