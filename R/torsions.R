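#' Signed dihedral angle
#'
#' Dihedral defined by four points, IUPAC sign convention: 0 for the cis
#' (eclipsed) arrangement, positive clockwise looking from `p2` towards
#' `p3`; result in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   # 0 (cis)
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180 (trans)
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  nb1 <- sqrt(sum(b1^2))
  if (nb1 < 1e-9)
    stop("degenerate dihedral: p2 and p3 coincide", call. = FALSE)
  b1 <- b1 / nb1
  v <- b0 - sum(b0 * b1) * b1      # projections into the plane normal to b1
  w <- b2 - sum(b2 * b1) * b1
  if (sqrt(sum(v^2)) < 1e-9 || sqrt(sum(w^2)) < 1e-9)
    stop("degenerate dihedral: three collinear points", call. = FALSE)
  ang <- atan2(sum(.ag_cross(b1, v) * w), sum(v * w)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.ag_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Circular absolute deviation between two angles
#'
#' Smallest absolute angular difference on the circle, in [0, 180].
#'
#' @param angle,ref angles in degrees, each in (-180, 180].
#' @return deviation in degrees.
#' @examples
#' circular_deviation(170, -170)  # 20
#' @export
circular_deviation <- function(angle, ref) {
  d <- abs(angle - ref) %% 360
  pmin(d, 360 - d)
}

#' Named torsion specification
#'
#' A named dihedral given by four atom names, e.g. the alpha and beta
#' torsions along a sulfonamide linker (ring C - S - N - C and
#' S - N - C - ring C).
#'
#' @param name torsion label (e.g. `"alpha"`).
#' @param atoms character vector of four distinct atom names.
#' @return a `torsion_spec`.
#' @export
torsion_spec <- function(name, atoms) {
  stopifnot(length(atoms) == 4, !anyDuplicated(atoms))
  structure(list(name = name, atoms = as.character(atoms)),
            class = "torsion_spec")
}

#' Measure a named torsion in a pose
#'
#' @param pose an `agpose` or `agmol`.
#' @param spec a [torsion_spec()].
#' @return signed angle, degrees.
#' @export
measure_torsion <- function(pose, spec) {
  mol <- if (inherits(pose, "agpose")) pose$molecule else pose
  idx <- match(spec$atoms, mol$atoms$name)
  if (any(is.na(idx)))
    stop(sprintf("torsion '%s': atom '%s' not found in pose '%s'",
                 spec$name, spec$atoms[is.na(idx)][1], mol$title),
         call. = FALSE)
  xyz <- mol_coords(mol)
  dihedral(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
}

#' Torsion strain report against reference statistics
#'
#' Measures every named torsion in every pose and reports the circular
#' absolute deviation from user-supplied reference means (e.g. statistics
#' for identical fragments retrieved from a small-molecule structure
#' database).  The comparative mode flags which of two pose sets is more
#' relaxed (smaller mean deviation) per torsion.
#'
#' @param poses list of `agpose`, or (comparative mode) a named list of
#'   two such lists.
#' @param specs list of [torsion_spec()].
#' @param refs named numeric vector: reference mean angle (degrees, in
#'   (-180, 180]) per torsion name.
#' @return data.frame: set, pose, torsion, angle, ref, deviation.  In
#'   comparative mode the attribute `comparison` holds a per-torsion
#'   data.frame with mean deviations and the more-relaxed set.
#' @export
strain_report <- function(poses, specs, refs) {
  sets <- if (length(poses) && inherits(poses[[1]], "agpose"))
    list(poses = poses) else poses
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  rows <- list()
  for (sname in names(sets)) {
    ps <- sets[[sname]]
    for (k in seq_along(ps)) {
      mol <- ps[[k]]$molecule
      for (sp in specs) {
        if (!sp$name %in% names(refs))
          stop("no reference mean for torsion: ", sp$name, call. = FALSE)
        ang <- measure_torsion(ps[[k]], sp)
        rows[[length(rows) + 1L]] <- data.frame(
          set = sname, pose = sprintf("pose_%04d", k), title = mol$title,
          torsion = sp$name, angle = ang, ref = refs[[sp$name]],
          deviation = circular_deviation(ang, refs[[sp$name]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(sets) == 2) {
    comp <- do.call(rbind, lapply(unique(out$torsion), function(tn) {
      m <- tapply(out$deviation[out$torsion == tn],
                  out$set[out$torsion == tn], mean)
      data.frame(torsion = tn, set_a = names(sets)[1], set_b = names(sets)[2],
                 mean_dev_a = as.numeric(m[[names(sets)[1]]]),
                 mean_dev_b = as.numeric(m[[names(sets)[2]]]),
                 more_relaxed = names(sets)[which.min(
                   c(m[[names(sets)[1]]], m[[names(sets)[2]]]))],
                 stringsAsFactors = FALSE)
    }))
    attr(out, "comparison") <- comp
  }
  out
}
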