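# Seeded generators for every fixture class the pipeline needs: toy
# receptor-ligand-water complexes, poses with closed-form occupancies,
# labeled molecule libraries, mutant structure pairs, and conformers with
# set torsions.  Geometry is idealized toy geometry (documented), written
# through the real I/O layer so parsing is exercised wherever fixtures are
# used.  Ground-truth labels are computed by independent arithmetic (lens
# volume closed form, fragment mass bookkeeping, brute-force distance
# loops), never by the analysis functions under test.

# deterministic unit directions roughly uniform on the sphere
.ag_fib_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# rotation taking unit vector a to unit vector b (Rodrigues)
.ag_rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- .ag_cross(a, b); c_ <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-12)
    return(if (c_ > 0) diag(3) else diag(c(1, -1, -1)))
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# idealized local-frame residue template: backbone + side chain marching
# from CB; toy geometry (bond-ish 1.4 A steps with a zig-zag), not
# stereochemically accurate
.ag_residue_template <- function(res_name) {
  stopifnot(res_name %in% .ag_standard_residues)
  bb <- rbind(N = c(-1.46, 0, 0), CA = c(0, 0, 0),
              C = c(0.53, 1.35, 0), O = c(1.66, 1.50, 0.45))
  sc_names <- .ag_res_sidechain[[res_name]]
  xyz <- bb
  if (length(sc_names)) {
    dir <- c(0.30, -0.55, -0.78); dir <- dir / sqrt(sum(dir^2))
    perp <- c(0.88, 0.40, 0.06); perp <- perp / sqrt(sum(perp^2))
    cb <- c(0.55, -0.75, -1.20)
    pos <- matrix(NA_real_, length(sc_names), 3,
                  dimnames = list(sc_names, NULL))
    for (k in seq_along(sc_names)) {
      pos[k, ] <- cb + (k - 1) * 1.40 * dir +
        ((k - 1) %% 2) * 0.45 * perp +
        ((k - 1) %/% 2 %% 2) * 0.35 * .ag_cross(dir, perp)
    }
    xyz <- rbind(bb, pos)
  }
  data.frame(name = rownames(xyz),
             element = .ag_atom_element_from_name(rownames(xyz)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

# place a residue template: CA at `ca`, side-chain axis toward `toward`
.ag_place_residue <- function(res_name, res_seq, chain, ca, toward) {
  tpl <- .ag_residue_template(res_name)
  axis0 <- c(0.30, -0.55, -0.78)
  R <- .ag_rot_between(axis0, toward - ca)
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(R)
  data.frame(record = "ATOM", name = tpl$name, res_name = res_name,
             chain = chain, res_seq = res_seq, insert = "",
             x = xyz[, 1] + ca[1], y = xyz[, 2] + ca[2], z = xyz[, 3] + ca[3],
             element = tpl$element, stringsAsFactors = FALSE)
}

# multi-atom reference ligand with ketone (O1), carboxylate-like oxygens
# (O3, O4 on C7) and a methyl carbon (C6); toy stand-in for the bound
# hormone
.ag_reference_ligand <- function(res_name = "ABA") {
  a <- rbind(
    C1 = c(0, 0, 0), O1 = c(0, 0, 1.23), C2 = c(1.45, 0, -0.45),
    C3 = c(2.45, 1.05, -0.10), C6 = c(-1.40, -0.40, -0.70),
    C7 = c(3.85, 0.80, -0.55), O3 = c(4.75, 1.65, -0.25),
    O4 = c(4.15, -0.20, -1.25))
  data.frame(record = "HETATM", name = rownames(a), res_name = res_name,
             chain = "A", res_seq = 501, insert = "",
             x = a[, 1], y = a[, 2], z = a[, 3],
             element = substr(rownames(a), 1, 1), stringsAsFactors = FALSE)
}

# corresponding bond graph (for graph-based ligand typing)
#' Bond graph of the generated reference ligand
#' @param res_name title for the molecule.
#' @return an `agmol` matching the ligand embedded by [make_toy_complex()].
#' @export
reference_ligand_mol <- function(res_name = "ABA") {
  lig <- .ag_reference_ligand(res_name)
  molecule(data.frame(element = lig$element, name = lig$name,
                      x = lig$x, y = lig$y, z = lig$z),
           bonds = data.frame(
             i = c(1, 1, 1, 3, 4, 6, 6),
             j = c(2, 3, 5, 4, 6, 7, 8),
             order = c(2, 1, 1, 1, 1, 2, 1)),
           title = res_name)
}

#' Generate a toy receptor-ligand-water complex
#'
#' Builds an idealized pocket: a multi-atom reference ligand at the
#' origin, `n_pocket_residues` protein residues placed on an inner shell
#' (heavy atoms within the 6 A band) and `n_outer_residues` on an outer
#' shell (beyond it), optional waters, and optionally an exactly
#' lock-satisfying water network (gate Pro117 backbone O, latch Arg145
#' backbone N, Trp385 NE1 on a second chain, water within H-bond distance
#' of all three plus the ligand carbonyl).  Residue numbering follows the
#' receptor convention used throughout the package (Lys88, Phe90, Val112,
#' Pro117, Glu123, Thr135, Phe137, Ile139, Arg145, Thr153, ...).
#'
#' Ground-truth pocket membership is recorded by an independent
#' brute-force distance scan at 6 A, not by [define_pocket()].
#'
#' @param seed integer seed; the generator is seed-deterministic.
#' @param n_pocket_residues inner-shell residue count (>= 3, <= 11).
#' @param n_outer_residues outer-shell residue count.
#' @param n_waters number of bulk waters.
#' @param with_trp_lock embed the lock water network.
#' @param ligand_res_name ligand residue name.
#' @param jitter_sigma Gaussian coordinate jitter, Angstrom.
#' @param path optional PDB output path; when given the file is written
#'   and re-read through [read_pdb()] so the returned structure has been
#'   through the real I/O layer.
#' @return an `agstruct` with attributes `pocket_truth` (res_keys of the
#'   in-pocket residues by brute force) and `lock_water_res_seq`.
#' @export
make_toy_complex <- function(seed = 1, n_pocket_residues = 8,
                             n_outer_residues = 4, n_waters = 3,
                             with_trp_lock = TRUE,
                             ligand_res_name = "ABA",
                             jitter_sigma = 0, path = NULL) {
  stopifnot(n_pocket_residues >= 3)
  rng <- .ag_rng(seed)
  inner_pool <- list(
    list(88, "LYS"), list(90, "PHE"), list(110, "VAL"), list(112, "VAL"),
    list(123, "GLU"), list(135, "THR"), list(137, "PHE"), list(139, "ILE"),
    list(149, "TYR"), list(153, "THR"), list(144, "HIS"))
  stopifnot(n_pocket_residues <= length(inner_pool))
  lig <- .ag_reference_ligand(ligand_res_name)
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  center <- colMeans(lig_xyz)
  dirs <- .ag_fib_sphere(n_pocket_residues + n_outer_residues)
  rows <- list(lig)
  for (k in seq_len(n_pocket_residues)) {
    ca <- center + dirs[k, ] * 7.5
    rows[[length(rows) + 1L]] <-
      .ag_place_residue(inner_pool[[k]][[2]], inner_pool[[k]][[1]], "A",
                        ca, center)
  }
  for (k in seq_len(n_outer_residues)) {
    ca <- center + dirs[n_pocket_residues + k, ] * 14.5
    rows[[length(rows) + 1L]] <-
      .ag_place_residue(c("VAL", "LEU", "SER", "GLY", "ALA")[(k - 1) %% 5 + 1],
                        167 + k, "A", ca, ca * 2 - center)
  }
  if (with_trp_lock) {
    o1 <- lig_xyz[lig$name == "O1", ]
    lock <- o1 + c(0, 1.6, 2.3)                     # 2.80 A from O1
    gate <- .ag_place_residue("PRO", 117, "A", lock + c(3.4, 1.6, 0.6),
                              center)
    gate[, c("x", "y", "z")] <- gate[, c("x", "y", "z")] -
      matrix(rep(as.numeric(gate[gate$name == "O", c("x", "y", "z")]) -
                   (lock + c(2.7, 0.6, 0.4)), each = nrow(gate)), ncol = 3)
    latch <- .ag_place_residue("ARG", 145, "A", lock + c(-3.2, 1.8, 0.5),
                               center)
    latch[, c("x", "y", "z")] <- latch[, c("x", "y", "z")] -
      matrix(rep(as.numeric(latch[latch$name == "N", c("x", "y", "z")]) -
                   (lock + c(-2.6, 0.9, 0.5)), each = nrow(latch)), ncol = 3)
    trp <- .ag_place_residue("TRP", 385, "B", lock + c(0.4, 5.6, 1.4),
                             lock)
    trp[, c("x", "y", "z")] <- trp[, c("x", "y", "z")] -
      matrix(rep(as.numeric(trp[trp$name == "NE1", c("x", "y", "z")]) -
                   (lock + c(0.3, 2.8, 0.8)), each = nrow(trp)), ncol = 3)
    wat <- data.frame(record = "HETATM", name = "O", res_name = "HOH",
                      chain = "S", res_seq = 601, insert = "",
                      x = lock[1], y = lock[2], z = lock[3], element = "O",
                      stringsAsFactors = FALSE)
    rows <- c(rows, list(gate, latch, trp, wat))
  }
  if (n_waters > 0) {
    wd <- .ag_fib_sphere(max(n_waters, 4))[seq_len(n_waters), , drop = FALSE]
    for (k in seq_len(n_waters)) {
      p <- center + wd[k, ] * (10.5 + 0.7 * k)
      rows[[length(rows) + 1L]] <- data.frame(
        record = "HETATM", name = "O", res_name = "HOH", chain = "S",
        res_seq = 601 + k, insert = "", x = p[1], y = p[2], z = p[3],
        element = "O", stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  if (jitter_sigma > 0) {
    at$x <- at$x + rng$norm(nrow(at)) * jitter_sigma
    at$y <- at$y + rng$norm(nrow(at)) * jitter_sigma
    at$z <- at$z + rng$norm(nrow(at)) * jitter_sigma
  }
  at[, c("x", "y", "z")] <- round(at[, c("x", "y", "z")], 3)  # PDB precision
  struct <- receptor_structure(at, source_id = sprintf("toy-complex-seed%d", seed))
  if (!is.null(path)) {
    write_pdb(struct, path)
    struct <- read_pdb(path, source_id = sprintf("toy-complex-seed%d", seed))
  }
  # brute-force ground truth at 6 A (independent of define_pocket)
  truth <- character()
  a <- struct$atoms
  ligsel <- a$res_name == ligand_res_name
  for (key in unique(a$res_key[!a$is_hetero & !a$is_water & !ligsel])) {
    ratoms <- which(a$res_key == key & a$element != "H")
    found <- FALSE
    for (i in ratoms) for (j in which(ligsel & a$element != "H")) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d <= 6.0) { found <- TRUE; break }
    }
    if (found) truth <- c(truth, key)
  }
  attr(struct, "pocket_truth") <- truth
  attr(struct, "lock_water_res_seq") <- if (with_trp_lock) 601L else NA_integer_
  struct
}

# local RNG that never touches the global .Random.seed
.ag_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(norm = function(n) with_state(function() stats::rnorm(n)),
       unif = function(n) with_state(function() stats::runif(n)),
       int = function(n, max) with_state(function()
         sample.int(max, n, replace = TRUE)))
}

#' Place a single-atom pose at a target sphere occupancy
#'
#' Solves the closed-form lens-volume equation ([lens_volume()]) for the
#' center distance `d` at which one atom of the given element occupies
#' `target_percent` of the sphere, by bisection to 1e-9 A, and places the
#' atom at that distance along +x from the sphere center.
#'
#' @param sphere a [pharmacophore_sphere()].
#' @param target_percent target occupancy in [0, 100].
#' @param atom_element element of the placed atom; must qualify for the
#'   sphere's required property (O for hba/hbd-with-H, C for hydrophobic).
#' @return an `agpose` with attribute `placed_distance`.
#' @export
make_pose_with_occupancy <- function(sphere, target_percent,
                                     atom_element = "O") {
  stopifnot(target_percent >= 0, target_percent <= 100)
  r <- vdw_radius(atom_element)
  R <- sphere$radius
  vs <- 4 / 3 * pi * R^3
  max_frac <- 100 * lens_volume(R, r, 0) / vs
  if (target_percent > max_frac + 1e-9)
    stop(sprintf("target %.1f%% infeasible: one %s atom covers at most %.1f%%",
                 target_percent, atom_element, max_frac), call. = FALSE)
  d <- if (target_percent == 0) R + r + 0.5
  else if (target_percent >= max_frac - 1e-12) 0
  else {
    lo <- if (r >= R) r - R else 0   # fully-inside regime boundary
    hi <- R + r
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      f <- 100 * lens_volume(R, r, mid) / vs
      if (f > target_percent) lo <- mid else hi <- mid
      if (hi - lo < 1e-12) break
    }
    (lo + hi) / 2
  }
  mol <- molecule(data.frame(element = atom_element,
                             name = paste0(atom_element, "1"),
                             x = sphere$center[1] + d,
                             y = sphere$center[2], z = sphere$center[3]),
                  title = sprintf("occ_%s_%.4f", sphere$name, target_percent))
  pose <- ligand_pose(mol)
  attr(pose, "placed_distance") <- d
  pose
}

# --- fragment set for the library generator ---------------------------------
# Each fragment: atoms (element, charge), bonds, join atom indices (left,
# right; NA right = terminal cap), free-molecule mass (fragment + capping
# hydrogens, IUPAC masses), and HBD/HBA contributions under the package's
# typing convention.  Contributions were cross-checked against an
# independent SMARTS implementation of the same convention; join atoms are
# constrained so assembly never changes a contribution (hetero join atoms
# only ever bond to sp3 carbon join atoms).
.ag_fragments <- function() {
  list(
    ph = list(el = rep("C", 6),
              bonds = data.frame(i = 1:6, j = c(2:6, 1),
                                 order = c(2, 1, 2, 1, 2, 1)),
              left = 1, right = 4, hbd = 0, hba = 0, sp2_join = TRUE),
    et = list(el = c("C", "C"),
              bonds = data.frame(i = 1, j = 2, order = 1),
              left = 1, right = 2, hbd = 0, hba = 0, sp2_join = FALSE),
    keto = list(el = c("C", "C", "O", "C"),
                bonds = data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                                   order = c(1, 2, 1)),
                left = 1, right = 4, hbd = 0, hba = 1, sp2_join = FALSE),
    eth = list(el = "O", bonds = NULL, left = 1, right = 1,
               hbd = 0, hba = 1, sp2_join = FALSE, hetero_join = TRUE),
    so2nh = list(el = c("S", "O", "O", "N"),
                 bonds = data.frame(i = c(1, 1, 1), j = c(2, 3, 4),
                                    order = c(2, 2, 1)),
                 left = 1, right = 4, hbd = 1, hba = 3, sp2_join = FALSE,
                 hetero_join = TRUE),
    me = list(el = "C", bonds = NULL, left = 1, right = NA,
              hbd = 0, hba = 0, sp2_join = FALSE),
    oh = list(el = c("C", "O"),
              bonds = data.frame(i = 1, j = 2, order = 1),
              left = 1, right = NA, hbd = 1, hba = 1, sp2_join = FALSE),
    cooh = list(el = c("C", "O", "O"),
                bonds = data.frame(i = c(1, 1), j = c(2, 3),
                                   order = c(2, 1)),
                left = 1, right = NA, hbd = 1, hba = 2, sp2_join = FALSE,
                carbonyl_join = TRUE),
    conh2 = list(el = c("C", "O", "N"),
                 bonds = data.frame(i = c(1, 1), j = c(2, 3),
                                    order = c(2, 1)),
                 left = 1, right = NA, hbd = 1, hba = 1, sp2_join = FALSE,
                 carbonyl_join = TRUE),
    nme2 = list(el = c("N", "C", "C"),
                bonds = data.frame(i = c(1, 1), j = c(2, 3), order = 1),
                left = 1, right = NA, hbd = 0, hba = 0, sp2_join = FALSE,
                hetero_join = TRUE),
    cl = list(el = "Cl", bonds = NULL, left = 1, right = NA,
              hbd = 0, hba = 0, sp2_join = FALSE, hetero_join = TRUE)
  )
}

# free-molecule monoisotopic-free standard mass of a fragment (fragment
# atoms + enough H to satisfy the valence model when unjoined)
.ag_fragment_free_mass <- function(fr) {
  atoms <- data.frame(element = fr$el, name = paste0(fr$el, seq_along(fr$el)),
                      x = seq_along(fr$el) * 1.5, y = 0, z = 0)
  m <- molecule(atoms, fr$bonds, title = "frag")
  molecular_weight(m)
}

#' Generate a labeled synthetic molecule library
#'
#' Assembles `n` molecules from a template fragment set (aromatic ring,
#' alkyl and ether linkers, ketone, sulfonamide, and terminal caps:
#' methyl, hydroxyl, carboxylic acid, amide, dimethylamino, chloro)
#' joined by single bonds.  Every molecule's true molecular weight and
#' donor/acceptor counts are computed by fragment-mass bookkeeping
#' (free-fragment mass minus 1.008 per hydrogen lost at each join;
#' per-fragment HBD/HBA contributions), independent of the typing module.
#' Hetero-join fragments are never placed adjacent to one another or to
#' an aromatic join carbon, so contributions are context-free.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed; byte-identical SDF for identical inputs.
#' @param n_frag_range inclusive range of fragment counts per molecule.
#' @param sdf_out optional path: write the library through [write_sdf()].
#' @return list with `poses` (list of `agpose`) and `labels` (data.frame
#'   title, mw, hbd, hba, pass at the shipped [filter_criteria()]).
#' @export
make_library <- function(n = 200, seed = 1, n_frag_range = c(2, 7),
                         sdf_out = NULL) {
  stopifnot(n >= 1)
  rng <- .ag_rng(seed)
  frs <- .ag_fragments()
  caps <- names(frs)[vapply(frs, function(f) is.na(f$right), TRUE)]
  links <- setdiff(names(frs), caps)
  is_het <- vapply(frs, function(f) isTRUE(f$hetero_join), TRUE)
  is_sp2 <- vapply(frs, function(f) isTRUE(f$sp2_join), TRUE)
  is_carb <- vapply(frs, function(f) isTRUE(f$carbonyl_join), TRUE)
  crit <- filter_criteria()
  poses <- vector("list", n)
  labels <- vector("list", n)
  for (m in seq_len(n)) {
    k <- n_frag_range[1] + rng$int(1, n_frag_range[2] - n_frag_range[1] + 1) - 1
    # chain of k-1 linkers + terminal cap; adjacency: never hetero-hetero
    # or hetero-sp2
    seq_names <- character(k)
    for (p in seq_len(k)) {
      pool <- if (p == k) caps else links
      repeat {
        cand <- pool[rng$int(1, length(pool))]
        if (p == 1 && is_het[cand]) next
        if (p > 1) {
          prev <- seq_names[p - 1]
          if (is_het[prev] && (is_het[cand] || is_sp2[cand] ||
                                 is_carb[cand])) next
          if (is_het[cand] && is_sp2[prev]) next
        }
        seq_names[p] <- cand
        break
      }
    }
    atoms <- NULL; bonds <- NULL
    offset <- 0; xoff <- 0
    joins <- 0L; mw <- 0; hbd <- 0L; hba <- 0L
    prev_right <- NA_integer_
    for (p in seq_len(k)) {
      fr <- frs[[seq_names[p]]]
      na <- length(fr$el)
      atoms <- rbind(atoms, data.frame(
        element = fr$el,
        name = paste0(fr$el, offset + seq_len(na)),
        x = xoff + seq_len(na) * 1.5, y = (p %% 2) * 0.8, z = 0))
      if (!is.null(fr$bonds))
        bonds <- rbind(bonds, data.frame(i = fr$bonds$i + offset,
                                         j = fr$bonds$j + offset,
                                         order = fr$bonds$order))
      if (!is.na(prev_right)) {
        bonds <- rbind(bonds, data.frame(i = prev_right,
                                         j = fr$left + offset, order = 1))
        joins <- joins + 1L
      }
      mw <- mw + .ag_fragment_free_mass(fr)
      hbd <- hbd + fr$hbd; hba <- hba + fr$hba
      prev_right <- if (is.na(fr$right)) NA_integer_ else fr$right + offset
      offset <- offset + na
      xoff <- xoff + na * 1.5 + 0.8
    }
    mw <- mw - 2 * joins * .ag_atomic_mass[["H"]]
    title <- sprintf("lib_%04d_%s", m, paste(seq_names, collapse = "-"))
    mol <- molecule(atoms, bonds, title = title)
    poses[[m]] <- ligand_pose(mol)
    pass <- mw >= crit$mw_min && mw <= crit$mw_max && hbd <= crit$hbd_max &&
      hba >= crit$hba_min && hba <= crit$hba_max
    labels[[m]] <- data.frame(title = title, mw = mw, hbd = hbd, hba = hba,
                              pass = pass, stringsAsFactors = FALSE)
  }
  labels <- do.call(rbind, labels)
  if (!is.null(sdf_out)) write_sdf(poses, sdf_out)
  list(poses = poses, labels = labels)
}

#' Substitute a residue's side chain in a toy structure
#'
#' Keeps the backbone (N, CA, C, O) and replaces the side chain with the
#' idealized template of `new_res_name`, oriented along the old CA->CB
#' direction (or a default direction for glycine).
#'
#' @param struct an `agstruct` built by [make_toy_complex()].
#' @param res_seq author residue number to substitute.
#' @param new_res_name target 3-letter residue name.
#' @return modified `agstruct`.
#' @export
substitute_residue <- function(struct, res_seq, new_res_name) {
  if (!new_res_name %in% .ag_standard_residues)
    stop("unknown residue template: ", new_res_name, call. = FALSE)
  at <- struct$atoms
  sel <- which(at$res_seq == res_seq & !at$is_water & !at$is_hetero)
  if (!length(sel)) stop("substitution position not found: ", res_seq,
                         call. = FALSE)
  ca <- as.numeric(at[sel[at$name[sel] == "CA"], c("x", "y", "z")])
  cb_row <- sel[at$name[sel] == "CB"]
  toward <- if (length(cb_row))
    ca + (as.numeric(at[cb_row, c("x", "y", "z")]) - ca) * 4
  else ca + c(0.30, -0.55, -0.78)
  chain <- at$chain[sel[1]]
  cols <- c("record", "name", "res_name", "chain", "res_seq", "insert",
            "x", "y", "z", "element")
  keep_bb <- at[sel[at$name[sel] %in% c("N", "CA", "C", "O")], cols,
                drop = FALSE]
  keep_bb$res_name <- new_res_name
  new_res <- .ag_place_residue(new_res_name, res_seq, chain, ca, toward)
  new_sc <- new_res[!(new_res$name %in% c("N", "CA", "C", "O")), cols,
                    drop = FALSE]
  if (nrow(new_sc))
    new_sc[, c("x", "y", "z")] <- round(new_sc[, c("x", "y", "z")], 3)
  rest <- at[-sel, cols, drop = FALSE]
  n_before <- sel[1] - 1L
  merged <- rbind(rest[seq_len(n_before), , drop = FALSE],
                  keep_bb, new_sc,
                  if (n_before < nrow(rest))
                    rest[seq(n_before + 1L, nrow(rest)), , drop = FALSE])
  receptor_structure(merged, source_id = struct$source_id)
}

#' Generate a homologous structure pair differing at known residues
#'
#' Copies a base toy complex and applies the listed side-chain
#' substitutions (emulating the pocket comparison between a receptor and
#' its engineered variant), plus optional Gaussian coordinate jitter on
#' the copy.  The ground-truth substitution list is attached.
#'
#' @param base_complex an `agstruct` from [make_toy_complex()].
#' @param substitutions data.frame with columns `res_seq`, `new_res_name`.
#' @param jitter_sigma Gaussian jitter on the copy's coordinates,
#'   Angstrom.
#' @param seed jitter seed.
#' @return list with `a` (base) and `b` (substituted copy), the latter
#'   carrying attribute `substitution_truth`.
#' @export
make_mutant_pair <- function(base_complex, substitutions,
                             jitter_sigma = 0, seed = 1) {
  b <- base_complex
  if (!is.null(substitutions) && nrow(substitutions)) {
    for (k in seq_len(nrow(substitutions)))
      b <- substitute_residue(b, substitutions$res_seq[k],
                              substitutions$new_res_name[k])
  }
  if (jitter_sigma > 0) {
    rng <- .ag_rng(seed)
    b$atoms$x <- b$atoms$x + rng$norm(nrow(b$atoms)) * jitter_sigma
    b$atoms$y <- b$atoms$y + rng$norm(nrow(b$atoms)) * jitter_sigma
    b$atoms$z <- b$atoms$z + rng$norm(nrow(b$atoms)) * jitter_sigma
  }
  b$source_id <- paste0(base_complex$source_id, "-mutant")
  attr(b, "substitution_truth") <- substitutions
  list(a = base_complex, b = b)
}

#' Template ligand with a sulfonamide linker
#'
#' Phenyl-SO2-NH-CH2-phenyl, the linker pattern whose alpha
#' (ring C-S-N-C) and beta (S-N-C-ring C) torsions characterize agonist
#' conformations.  Built in an arbitrary starting conformation; use
#' [make_conformer()] to set torsions.
#'
#' @return an `agmol` with named atoms (C1..C6 ring A, S1, OS1, OS2, N1,
#'   C7 methylene, C8..C13 ring B).
#' @export
sulfonamide_template <- function() {
  deg <- pi / 180
  ringA <- t(vapply(0:5, function(k)
    c(cos(60 * k * deg) * 1.39 - 3.3, sin(60 * k * deg) * 1.39, 0),
    numeric(3)))
  s <- c(-0.2, 0, 0.5)
  os1 <- s + c(-0.3, -1.25, 0.7); os2 <- s + c(-0.9, 0.7, -1.0)
  n1 <- s + c(0.6, 1.45, 0.2)
  c7 <- n1 + c(1.2, 0.8, -0.3)
  dirB <- c(1, 0.35, -0.25); dirB <- dirB / sqrt(sum(dirB^2))
  cB <- c7 + dirB * 2.2
  ex <- dirB; ey <- c(-dirB[2], dirB[1], 0); ey <- ey / sqrt(sum(ey^2))
  ringB <- t(vapply(0:5, function(k)
    cB + 1.39 * (cos(60 * k * deg) * ex + sin(60 * k * deg) * ey),
    numeric(3)))
  xyz <- rbind(ringA, s, os1, os2, n1, c7, ringB)
  nm <- c(paste0("C", 1:6), "S1", "OS1", "OS2", "N1", "C7", paste0("C", 8:13))
  el <- c(rep("C", 6), "S", "O", "O", "N", "C", rep("C", 6))
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 1, 7, 7, 7, 10, 11, 12, 13, 14, 15, 16, 17),
    j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 12),
    order = c(2, 1, 2, 1, 2, 1, 1, 2, 2, 1, 1, 1, 2, 1, 2, 1, 2, 1))
  molecule(data.frame(element = el, name = nm, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3]),
           bonds, title = "sulfonamide_template")
}

#' Default alpha/beta torsion specs for the sulfonamide linker
#'
#' Illustrative atom quadruples for the linker torsions: alpha =
#' C2-C1-S1-N1 (about the aryl-S bond... measured about S1-N1 here as
#' C1-S1-N1-C7) and beta = S1-N1-C7-C8.
#'
#' @return list of two [torsion_spec()] objects named alpha and beta.
#' @export
sulfonamide_torsion_specs <- function() {
  list(torsion_spec("alpha", c("C1", "S1", "N1", "C7")),
       torsion_spec("beta", c("S1", "N1", "C7", "C8")))
}

#' Build a conformer with set torsions
#'
#' Rotates, for each named torsion in `assignments`, the atoms downstream
#' of the torsion's central bond so the measured dihedral equals the
#' assigned value.  The central bond must be acyclic (rotatable).
#' Assignments on independent (non-nested) bonds are applied in spec
#' order; re-measuring each set torsion returns the assigned value to
#' 1e-6 degrees.
#'
#' @param template an `agmol`.
#' @param assignments named numeric vector, degrees in (-180, 180];
#'   names must match `specs`.
#' @param specs list of [torsion_spec()]; default
#'   [sulfonamide_torsion_specs()].
#' @return an `agpose` with the rotated coordinates.
#' @export
make_conformer <- function(template, assignments,
                           specs = sulfonamide_torsion_specs()) {
  mol <- template
  spec_names <- vapply(specs, `[[`, "", "name")
  for (tn in names(assignments)) {
    sp <- specs[[match(tn, spec_names)]]
    if (is.na(match(tn, spec_names)))
      stop("no torsion spec named ", tn, call. = FALSE)
    idx <- match(sp$atoms, mol$atoms$name)
    if (any(is.na(idx)))
      stop("torsion atom not found: ", sp$atoms[is.na(idx)][1], call. = FALSE)
    b2 <- idx[2]; b3 <- idx[3]
    # downstream component of b3 with the central bond removed
    nb <- .ag_neighbors(mol)
    seen <- rep(FALSE, nrow(mol$atoms))
    stack <- b3; seen[b3] <- TRUE
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      for (w in nb[[v]]) {
        if (v == b3 && w == b2) next
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    if (seen[b2])
      stop(sprintf("torsion '%s': central bond %s-%s is in a ring (not rotatable)",
                   tn, sp$atoms[2], sp$atoms[3]), call. = FALSE)
    rot_set <- which(seen & seq_len(nrow(mol$atoms)) != b3)
    cur <- measure_torsion(mol, sp)
    # a right-hand rotation of the downstream side about b2->b3 by delta
    # increases the signed dihedral by delta
    delta <- (assignments[[tn]] - cur) * pi / 180
    xyz <- mol_coords(mol)
    axis <- xyz[b3, ] - xyz[b2, ]; axis <- axis / sqrt(sum(axis^2))
    # Rodrigues rotation about the b2->b3 axis through b3
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(delta) * K + (1 - cos(delta)) * K %*% K
    pivot <- xyz[b3, ]
    moved <- sweep(sweep(xyz[rot_set, , drop = FALSE], 2, pivot) %*% t(R),
                   2, -pivot)
    mol$atoms$x[rot_set] <- moved[, 1]
    mol$atoms$y[rot_set] <- moved[, 2]
    mol$atoms$z[rot_set] <- moved[, 3]
  }
  ligand_pose(mol)
}
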