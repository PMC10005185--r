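#' Detect receptor-ligand hydrogen bonds
#'
#' Geometric heavy-atom criterion: a donor and an acceptor heavy atom
#' within `cutoff` Angstrom (default 3.5, inclusive).  Crystal structures
#' typically lack hydrogens, so the heavy-atom distance criterion is the
#' default; when an explicit hydrogen bonded to the donor is present the
#' D-H...A angle must additionally be at least `min_angle` degrees.
#' Protein atoms are typed by residue template, ligand atoms by the bond
#' graph ([type_atoms()]).
#'
#' @param complex an `agstruct` holding protein, ligand and waters.
#' @param ligand_res_name ligand residue name.
#' @param ligand_mol optional `agmol` giving the ligand's bond graph
#'   (atom names must match the PDB ligand atoms); when absent, ligand O
#'   and N atoms are treated as both donor and acceptor candidates.
#' @param cutoff heavy-atom donor-acceptor distance cutoff, Angstrom.
#' @param min_angle D-H...A angle cutoff, degrees (applied only when an
#'   explicit H is present).
#' @param include_waters logical; include protein-water / ligand-water
#'   bonds.
#' @return data.frame sorted by distance: donor_res, donor_atom,
#'   acceptor_res, acceptor_atom, distance, angle (NA without H),
#'   ligand_involved.
#' @export
find_hbonds <- function(complex, ligand_res_name, ligand_mol = NULL,
                        cutoff = 3.5, min_angle = 120,
                        include_waters = TRUE) {
  at <- complex$atoms
  typ <- .ag_complex_hbond_typing(complex, ligand_res_name, ligand_mol)
  if (!include_waters) {
    typ$donor[at$is_water] <- FALSE
    typ$acceptor[at$is_water] <- FALSE
  }
  don <- which(typ$donor)
  acc <- which(typ$acceptor)
  xyz <- struct_coords(at)
  hyd <- .ag_hydrogen_map(complex)
  rows <- list()
  for (d in don) {
    dv <- xyz[acc, , drop = FALSE]
    d2 <- (dv[, 1] - xyz[d, 1])^2 + (dv[, 2] - xyz[d, 2])^2 +
      (dv[, 3] - xyz[d, 3])^2
    hits <- acc[d2 <= cutoff^2]
    hits <- hits[hits != d & at$res_key[hits] != at$res_key[d]]
    for (a in hits) {
      ang <- .ag_dha_angle(xyz, d, a, hyd[[d]])
      if (!is.na(ang) && ang < min_angle) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_res = paste0(at$res_name[d], at$res_seq[d]),
        donor_atom = at$name[d],
        acceptor_res = paste0(at$res_name[a], at$res_seq[a]),
        acceptor_atom = at$name[a],
        distance = sqrt(sum((xyz[a, ] - xyz[d, ])^2)),
        angle = ang,
        ligand_involved = at$res_name[d] == ligand_res_name |
          at$res_name[a] == ligand_res_name,
        donor_idx = d, acceptor_idx = a, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_res = character(), donor_atom = character(),
               acceptor_res = character(), acceptor_atom = character(),
               distance = numeric(), angle = numeric(),
               ligand_involved = logical(), donor_idx = integer(),
               acceptor_idx = integer())
  out <- out[order(out$distance, out$donor_idx, out$acceptor_idx), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Donor/acceptor flags over the whole complex: protein by template,
# waters both, ligand by bond graph or element fallback.
.ag_complex_hbond_typing <- function(complex, ligand_res_name, ligand_mol) {
  at <- complex$atoms
  typ <- .ag_protein_hbond_typing(at)
  lig <- which(at$res_name == ligand_res_name)
  if (length(lig)) {
    if (!is.null(ligand_mol)) {
      lt <- type_atoms(ligand_mol)
      m <- match(at$name[lig], ligand_mol$atoms$name)
      if (any(is.na(m)))
        stop("ligand atom name not in ligand_mol: ",
             at$name[lig][is.na(m)][1], call. = FALSE)
      typ$donor[lig] <- lt$is_hbd[m]
      typ$acceptor[lig] <- lt$is_hba[m]
    } else {
      polar <- at$element[lig] %in% c("N", "O")
      typ$donor[lig] <- polar
      typ$acceptor[lig] <- polar
    }
  }
  typ
}

# explicit hydrogens attached to each heavy atom (same residue, within
# 1.3 A) -- empty for H-less crystal structures
.ag_hydrogen_map <- function(complex) {
  at <- complex$atoms
  xyz <- struct_coords(at)
  hs <- which(at$element == "H")
  out <- vector("list", nrow(at))
  for (h in hs) {
    same <- which(at$res_key == at$res_key[h] & at$element != "H")
    if (!length(same)) next
    d2 <- rowSums((xyz[same, , drop = FALSE] -
                     matrix(xyz[h, ], length(same), 3, byrow = TRUE))^2)
    k <- same[which.min(d2)]
    if (min(d2) <= 1.3^2) out[[k]] <- c(out[[k]], h)
  }
  out
}

.ag_dha_angle <- function(xyz, d, a, hs) {
  if (is.null(hs) || !length(hs)) return(NA_real_)
  best <- NA_real_
  for (h in hs) {
    v1 <- xyz[d, ] - xyz[h, ]
    v2 <- xyz[a, ] - xyz[h, ]
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (is.na(best) || ang > best) best <- ang
  }
  best
}

#' Detect water-mediated bridges between ligand and protein
#'
#' A bridge is a water whose oxygen lies within H-bond distance
#' (`cutoff`, heavy-atom criterion) of a polar ligand atom and of a
#' polar protein atom.
#'
#' @inheritParams find_hbonds
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @return data.frame: water_res_seq, ligand_atom, ligand_dist,
#'   protein_res, protein_atom, protein_dist.
#' @export
find_water_bridges <- function(complex, ligand_res_name, ligand_mol = NULL,
                               cutoff = 3.5) {
  at <- complex$atoms
  typ <- .ag_complex_hbond_typing(complex, ligand_res_name, ligand_mol)
  polar <- typ$donor | typ$acceptor
  xyz <- struct_coords(at)
  waters <- which(at$is_water & at$element == "O")
  lig <- which(at$res_name == ligand_res_name & polar)
  prot <- which(!at$is_water & at$res_name != ligand_res_name & polar &
                  at$res_name %in% .ag_standard_residues)
  rows <- list()
  for (w in waters) {
    dl <- sqrt(colSums((t(xyz[lig, , drop = FALSE]) - xyz[w, ])^2))
    dp <- sqrt(colSums((t(xyz[prot, , drop = FALSE]) - xyz[w, ])^2))
    li <- which(dl <= cutoff)
    pi_ <- which(dp <= cutoff)
    for (i in li) for (j in pi_) {
      rows[[length(rows) + 1L]] <- data.frame(
        water_res_seq = at$res_seq[w],
        ligand_atom = at$name[lig[i]], ligand_dist = dl[i],
        protein_res = paste0(at$res_name[prot[j]], at$res_seq[prot[j]]),
        protein_atom = at$name[prot[j]], protein_dist = dp[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(water_res_seq = integer(), ligand_atom = character(),
               ligand_dist = numeric(), protein_res = character(),
               protein_atom = character(), protein_dist = numeric())
}

#' Motif pattern for water-centered interaction networks
#'
#' A named pattern with participant slots and pairwise distance bounds.
#' The shipped `trp_lock_pattern()` encodes the water-mediated lock
#' joining the ligand carbonyl oxygen, the latch backbone amine, the gate
#' backbone carbonyl and the phosphatase tryptophan side chain.
#'
#' @param name pattern label.
#' @param slots named list of slot selectors, each a list with fields
#'   `res_name` (or `ligand = TRUE`), optional `res_seq`, and `atom`
#'   (atom-name vector) or `element`.
#' @param constraints data.frame with columns slot_a, slot_b, max_dist
#'   (and optional min_dist).
#' @return a `motif_pattern`.
#' @export
motif_pattern <- function(name, slots, constraints) {
  stopifnot(length(slots) >= 2, all(c(constraints$slot_a, constraints$slot_b)
                                    %in% names(slots)))
  # constraint graph must be connected
  g <- unique(rbind(as.matrix(constraints[, c("slot_a", "slot_b")])))
  reach <- names(slots)[1]
  repeat {
    add <- unique(c(g[g[, 1] %in% reach, 2], g[g[, 2] %in% reach, 1]))
    add <- setdiff(add, reach)
    if (!length(add)) break
    reach <- c(reach, add)
  }
  if (!setequal(reach, names(slots)))
    stop("motif constraint graph is not connected", call. = FALSE)
  structure(list(name = name, slots = slots, constraints = constraints),
            class = "motif_pattern")
}

#' The Trp-lock motif pattern
#'
#' Water O within H-bond distance of: the ligand carbonyl O, the latch
#' residue backbone N, the gate residue backbone O, and the Trp side-chain
#' NE1.
#'
#' @param ligand_res_name ligand residue name.
#' @param carbonyl_atom ligand carbonyl oxygen atom name.
#' @param latch_res_seq,gate_res_seq,trp_res_seq author residue numbers of
#'   the latch, gate and tryptophan residues (defaults 145, 117, 385).
#' @param hbond_dist distance bound, Angstrom.
#' @return a [motif_pattern()].
#' @export
trp_lock_pattern <- function(ligand_res_name = "LIG", carbonyl_atom = "O1",
                             latch_res_seq = 145, gate_res_seq = 117,
                             trp_res_seq = 385, hbond_dist = 3.5) {
  motif_pattern(
    "trp_lock",
    slots = list(
      water = list(res_name = "HOH", atom = "O"),
      lig_carbonyl = list(res_name = ligand_res_name, atom = carbonyl_atom),
      latch_n = list(res_seq = latch_res_seq, atom = "N"),
      gate_o = list(res_seq = gate_res_seq, atom = "O"),
      trp_ne1 = list(res_name = "TRP", res_seq = trp_res_seq, atom = "NE1")),
    constraints = data.frame(
      slot_a = "water",
      slot_b = c("lig_carbonyl", "latch_n", "gate_o", "trp_ne1"),
      max_dist = hbond_dist))
}

#' Match a motif pattern in a complex
#'
#' Enumerates every assignment of structure atoms to pattern slots that
#' satisfies all pairwise distance constraints.
#'
#' @param complex an `agstruct`.
#' @param pattern a [motif_pattern()].
#' @return data.frame with one row per match; columns `<slot>_res_seq`,
#'   `<slot>_atom` per slot.
#' @export
match_motif <- function(complex, pattern) {
  at <- complex$atoms
  xyz <- struct_coords(at)
  cand <- lapply(pattern$slots, function(sl) {
    sel <- rep(TRUE, nrow(at))
    if (!is.null(sl$res_name)) sel <- sel & at$res_name == sl$res_name
    if (!is.null(sl$res_seq)) sel <- sel & at$res_seq %in% sl$res_seq
    if (!is.null(sl$atom)) sel <- sel & at$name %in% sl$atom
    if (!is.null(sl$element)) sel <- sel & at$element %in% sl$element
    which(sel)
  })
  empty <- vapply(cand, length, 1L) == 0
  if (any(empty))
    stop("motif slot has no candidate atoms: ",
         names(cand)[empty][1], call. = FALSE)
  slots <- names(pattern$slots)
  cons <- pattern$constraints
  if (is.null(cons$min_dist)) cons$min_dist <- 0
  assign_ok <- function(part) {
    for (k in seq_len(nrow(cons))) {
      ia <- part[[cons$slot_a[k]]]; ib <- part[[cons$slot_b[k]]]
      if (is.null(ia) || is.null(ib)) next
      d <- sqrt(sum((xyz[ia, ] - xyz[ib, ])^2))
      if (d > cons$max_dist[k] || d < cons$min_dist[k]) return(FALSE)
    }
    TRUE
  }
  matches <- list()
  recurse <- function(part, depth) {
    if (depth > length(slots)) {
      matches[[length(matches) + 1L]] <<- unlist(part)
      return(invisible())
    }
    sl <- slots[depth]
    for (a in cand[[sl]]) {
      if (a %in% unlist(part)) next
      part[[sl]] <- a
      if (assign_ok(part)) recurse(part, depth + 1L)
      part[[sl]] <- NULL
    }
  }
  recurse(list(), 1L)
  if (!length(matches)) {
    cols <- c(rbind(paste0(slots, "_res_seq"), paste0(slots, "_atom")))
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                                dimnames = list(NULL, cols)))
    return(out)
  }
  out <- do.call(rbind, lapply(matches, function(m) {
    row <- list()
    for (sl in slots) {
      row[[paste0(sl, "_res_seq")]] <- at$res_seq[m[[sl]]]
      row[[paste0(sl, "_atom")]] <- at$name[m[[sl]]]
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hydrophobic contacts between a ligand and selected residues
#'
#' Pairs of apolar (C or S) heavy atoms -- one from the ligand, one from a
#' residue in `residue_set` -- within `cutoff` Angstrom (inclusive).
#' Counting contacts in a hydrophobic sub-pocket such as the 3' tunnel
#' rationalizes alkyl-substituent potency differences between agonists.
#'
#' @param complex an `agstruct`.
#' @param ligand_res_name ligand residue name.
#' @param residue_set integer vector of author residue numbers (or NULL
#'   for all protein residues).
#' @param cutoff contact distance, Angstrom.
#' @return list with `contacts` (data.frame ligand_atom, res, res_atom,
#'   distance) and `per_residue` (named counts) and `n_contacts`.
#' @export
hydrophobic_contacts <- function(complex, ligand_res_name,
                                 residue_set = NULL, cutoff = 4.5) {
  at <- complex$atoms
  lig <- which(at$res_name == ligand_res_name & at$element %in% c("C", "S"))
  prot <- which(!at$is_water & at$res_name != ligand_res_name &
                  at$res_name %in% .ag_standard_residues &
                  at$element %in% c("C", "S"))
  if (!is.null(residue_set)) prot <- prot[at$res_seq[prot] %in% residue_set]
  xyz <- struct_coords(at)
  rows <- list()
  for (i in lig) {
    d <- sqrt(colSums((t(xyz[prot, , drop = FALSE]) - xyz[i, ])^2))
    for (j in which(d <= cutoff)) {
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_atom = at$name[i],
        res = paste0(at$res_name[prot[j]], at$res_seq[prot[j]]),
        res_atom = at$name[prot[j]], distance = d[j],
        stringsAsFactors = FALSE)
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ligand_atom = character(), res = character(),
               res_atom = character(), distance = numeric())
  per_res <- if (nrow(contacts)) table(contacts$res) else table(character())
  list(contacts = contacts,
       per_residue = stats::setNames(as.integer(per_res), names(per_res)),
       n_contacts = nrow(contacts))
}
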