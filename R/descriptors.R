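#' Pharmacophore sphere descriptor
#'
#' A sphere at a chemically meaningful anchor whose percent volume
#' occupied by ligand atoms of a required pharmacophoric property scores a
#' docked pose.
#'
#' @param name label.
#' @param center 3-vector, Angstrom, receptor frame.
#' @param radius sphere radius, Angstrom (> 0).
#' @param required_property one of `"hba"`, `"hbd"`, `"hydrophobic"`,
#'   `"any"`.
#' @return a `pharmacophore_sphere` object.
#' @export
pharmacophore_sphere <- function(name, center, radius,
                                 required_property = c("hba", "hbd",
                                                       "hydrophobic", "any")) {
  required_property <- match.arg(required_property)
  center <- as.numeric(center)
  stopifnot(length(center) == 3, all(is.finite(center)), radius > 0)
  structure(list(name = name, center = center, radius = radius,
                 required_property = required_property),
            class = "pharmacophore_sphere")
}

#' Build the default descriptor spheres from a reference complex
#'
#' Constructs the four sphere descriptors anchored on a bound reference
#' ligand (the natural hormone ABA in the published screen) and the
#' receptor pocket:
#'
#' * `keto_O`: hydrogen-bond acceptor sphere, radius 1.5 A, at the
#'   ligand's ketone oxygen.
#' * `carboxylate`: acceptor sphere, radius 2.8 A, at the carboxylate
#'   position (default: centroid of the two carboxylate oxygens; the
#'   carboxylate carbon or a single oxygen are selectable).
#' * `methyl`: hydrophobic sphere, radius 1.4 A, at a ligand methyl
#'   carbon named in the anchor spec.
#' * `pocket_centroid`: hydrophobic sphere, radius 3.5 A, at the centroid
#'   of the side-chain heavy atoms of two pocket residues (defaults
#'   F90 and I139).
#'
#' @param reference_complex an `agstruct` holding receptor + ligand.
#' @param ligand_res_name residue name of the reference ligand.
#' @param anchor_spec list naming the anchor atoms:
#'   `keto_atom` (default `"O1"`), `carboxylate_atoms` (default
#'   `c("O3","O4")`), `carboxylate_mode` (`"centroid"`, `"atom"`),
#'   `methyl_atom` (default `"C6"`), `pocket_residues` (default
#'   `c(90, 139)`, author numbering).  Radii and properties can be
#'   overridden via `radii` / `properties` named vectors.
#' @return list of four [pharmacophore_sphere()] objects.
#' @export
build_descriptors <- function(reference_complex, ligand_res_name = "ABA",
                              anchor_spec = list()) {
  spec <- utils::modifyList(list(
    keto_atom = "O1", carboxylate_atoms = c("O3", "O4"),
    carboxylate_mode = "centroid", methyl_atom = "C6",
    pocket_residues = c(90, 139),
    radii = c(keto_O = 1.5, carboxylate = 2.8, methyl = 1.4,
              pocket_centroid = 3.5),
    properties = c(keto_O = "hba", carboxylate = "hba",
                   methyl = "hydrophobic", pocket_centroid = "hydrophobic")
  ), anchor_spec)
  lig <- select_residue(reference_complex, ligand_res_name)
  anchor <- function(names) {
    hit <- lig[lig$name %in% names, , drop = FALSE]
    if (nrow(hit) < length(names))
      stop("anchor atom(s) not found in ligand ", ligand_res_name, ": ",
           paste(setdiff(names, hit$name), collapse = ", "), call. = FALSE)
    colMeans(struct_coords(hit))
  }
  carb <- switch(spec$carboxylate_mode,
                 centroid = anchor(spec$carboxylate_atoms),
                 atom = anchor(spec$carboxylate_atoms[1]),
                 stop("unknown carboxylate_mode", call. = FALSE))
  at <- reference_complex$atoms
  side <- at[at$res_seq %in% spec$pocket_residues & !at$is_hetero &
               at$element != "H" &
               !(at$name %in% c("N", "CA", "C", "O")), , drop = FALSE]
  if (nrow(side) == 0)
    stop("pocket residues not found: ",
         paste(spec$pocket_residues, collapse = ", "), call. = FALSE)
  list(
    pharmacophore_sphere("keto_O", anchor(spec$keto_atom),
                         spec$radii[["keto_O"]], spec$properties[["keto_O"]]),
    pharmacophore_sphere("carboxylate", carb, spec$radii[["carboxylate"]],
                         spec$properties[["carboxylate"]]),
    pharmacophore_sphere("methyl", anchor(spec$methyl_atom),
                         spec$radii[["methyl"]], spec$properties[["methyl"]]),
    pharmacophore_sphere("pocket_centroid", colMeans(struct_coords(side)),
                         spec$radii[["pocket_centroid"]],
                         spec$properties[["pocket_centroid"]])
  )
}

#' Closed-form sphere/sphere intersection (lens) volume
#'
#' Volume of the intersection of spheres of radii `R` and `r` whose
#' centers are `d` apart.  Used as the analytic reference for occupancy
#' sampling and to place single-atom fixtures at a target occupancy.
#'
#' @param R,r sphere radii, Angstrom.
#' @param d center distance, Angstrom.
#' @return volume, cubic Angstrom.
#' @export
lens_volume <- function(R, r, d) {
  stopifnot(R > 0, r > 0, d >= 0)
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(4 / 3 * pi * min(R, r)^3)
  pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
}

# Atoms that qualify for a sphere's required property.
.ag_qualifying <- function(mol, typing, property) {
  heavy <- is_heavy(mol)
  switch(property,
         hba = heavy & typing$is_hba,
         hbd = heavy & typing$is_hbd,
         hydrophobic = heavy & typing$is_hydrophobic,
         any = heavy)
}

#' Percent sphere volume occupied by qualifying pose atoms
#'
#' Fraction (as a percentage) of the sphere's volume lying inside the
#' union of van der Waals spheres of the pose's atoms that carry the
#' sphere's required property.  Hydrogens never contribute.  The default
#' sampler is a deterministic cubic grid aligned to the sphere center
#' (spacing 0.2 A); a seeded Monte Carlo sampler is available.
#'
#' @param sphere a [pharmacophore_sphere()].
#' @param pose an `agpose` (or `agmol`) in the same frame as the sphere.
#' @param typing optional precomputed [type_atoms()] for the molecule.
#' @param sampler `"grid"` or `"mc"`.
#' @param spacing grid spacing, Angstrom.
#' @param points Monte Carlo sample size.
#' @param seed Monte Carlo seed (required for `"mc"`).
#' @param vdw optional named radius overrides passed to [vdw_radius()].
#' @return percent in [0, 100].
#' @export
sphere_occupancy <- function(sphere, pose, typing = NULL,
                             sampler = c("grid", "mc"), spacing = 0.2,
                             points = 1e5, seed = NULL, vdw = NULL) {
  sampler <- match.arg(sampler)
  mol <- if (inherits(pose, "agpose")) pose$molecule else pose
  if (is.null(typing)) typing <- type_atoms(mol)
  qual <- .ag_qualifying(mol, typing, sphere$required_property)
  if (!any(qual)) return(0)
  xyz <- mol_coords(mol)[qual, , drop = FALSE]
  rad <- vdw_radius(mol$atoms$element[qual], vdw)
  # prune atoms that cannot reach the sphere
  dc <- sqrt(colSums((t(xyz) - sphere$center)^2))
  keep <- dc < sphere$radius + rad
  if (!any(keep)) return(0)
  xyz <- xyz[keep, , drop = FALSE]; rad <- rad[keep]
  if (sampler == "grid") {
    # cell-centered grid with deterministic 3x3x3 sub-cell refinement of
    # every cell straddling either the descriptor-sphere surface or an
    # atom surface; numerator and denominator are accumulated from the
    # same sub-samples, removing most of the O(spacing) surface bias of
    # plain point counting
    R <- sphere$radius
    margin <- spacing * sqrt(3) / 2
    g <- seq(-R - margin + spacing / 2, R + margin, by = spacing)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    rr <- sqrt(rowSums(pts^2))
    pts <- pts[rr <= R + margin, , drop = FALSE]
    rr <- rr[rr <= R + margin]
    pts <- sweep(pts, 2, -sphere$center)
    atom_signed <- rep(Inf, nrow(pts))  # min over atoms of (dist - vdW)
    for (a in seq_len(nrow(xyz))) {
      d <- sqrt((pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
                  (pts[, 3] - xyz[a, 3])^2) - rad[a]
      atom_signed <- pmin(atom_signed, d)
    }
    certain <- rr <= R - margin & abs(atom_signed) > margin
    num <- sum(atom_signed[certain] <= 0)
    den <- sum(certain)
    unc <- which(!certain)
    if (length(unc)) {
      off <- as.matrix(expand.grid(x = spacing / 3 * (-1:1),
                                   y = spacing / 3 * (-1:1),
                                   z = spacing / 3 * (-1:1)))
      nu <- length(unc)
      sub <- pts[rep(unc, each = 27), , drop = FALSE] +
        off[rep(seq_len(27), nu), , drop = FALSE]
      ctr <- sphere$center
      in_sph <- (sub[, 1] - ctr[1])^2 + (sub[, 2] - ctr[2])^2 +
        (sub[, 3] - ctr[3])^2 <= R^2
      in_uni <- rep(FALSE, nrow(sub))
      for (a in seq_len(nrow(xyz))) {
        idx <- which(!in_uni & in_sph)
        if (!length(idx)) break
        d2 <- (sub[idx, 1] - xyz[a, 1])^2 + (sub[idx, 2] - xyz[a, 2])^2 +
          (sub[idx, 3] - xyz[a, 3])^2
        in_uni[idx[d2 <= rad[a]^2]] <- TRUE
      }
      num <- num + sum(in_sph & in_uni) / 27
      den <- den + sum(in_sph) / 27
    }
    return(if (den == 0) 0 else 100 * num / den)
  }
  pts <- {
    if (is.null(seed)) stop("Monte Carlo sampler requires a seed", call. = FALSE)
    old <- exists(".Random.seed", envir = globalenv())
    if (old) saved <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    u <- matrix(stats::rnorm(points * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rr <- sphere$radius * stats::runif(points)^(1 / 3)
    pts <- u * rr
    if (old) assign(".Random.seed", saved, envir = globalenv())
    sweep(pts, 2, -sphere$center)
  }
  inside <- rep(FALSE, nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    idx <- which(!inside)
    if (!length(idx)) break
    d2 <- (pts[idx, 1] - xyz[a, 1])^2 + (pts[idx, 2] - xyz[a, 2])^2 +
      (pts[idx, 3] - xyz[a, 3])^2
    inside[idx[d2 <= rad[a]^2]] <- TRUE
  }
  100 * mean(inside)
}

#' Score docked poses against descriptor spheres
#'
#' One row per pose with the percent occupancy of every sphere and the
#' pose's external docking score.  Deterministic under the grid sampler
#' and under a fixed Monte Carlo seed.
#'
#' @param poses list of `agpose`.
#' @param spheres list of [pharmacophore_sphere()].
#' @param ... sampler options forwarded to [sphere_occupancy()].
#' @return data.frame with columns pose_id, title, docking_score and one
#'   `occ_<sphere name>` column per sphere.
#' @export
score_poses <- function(poses, spheres, ...) {
  rows <- lapply(seq_along(poses), function(k) {
    p <- poses[[k]]
    typing <- type_atoms(p$molecule)
    occ <- vapply(spheres, function(s)
      sphere_occupancy(s, p, typing = typing, ...), numeric(1))
    names(occ) <- paste0("occ_", vapply(spheres, `[[`, "", "name"))
    cbind(data.frame(pose_id = sprintf("pose_%04d", k),
                     title = p$molecule$title,
                     docking_score = p$docking_score),
          as.data.frame(as.list(occ)))
  })
  do.call(rbind, rows)
}
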