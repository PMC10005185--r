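# Independent oracles used across the suite.  These deliberately do not
# share code paths with the package internals they check.

# Closed-form sphere-intersection fraction via the two-spherical-caps
# formulation (independent of lens_volume()'s single-expression form).
oracle_lens_fraction <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(min(1, (r / R)^3))
  cap <- function(rad, h) pi * h^2 * (3 * rad - h) / 3
  x <- (d^2 - r^2 + R^2) / (2 * d)   # plane offset from center of R-sphere
  v <- cap(R, R - x) + cap(r, r - (d - x))
  v / (4 / 3 * pi * R^3)
}

# Horn's quaternion method for least-squares rigid superposition.
oracle_quaternion_superpose <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  A <- sweep(xa, 2, ca); B <- sweep(xb, 2, cb)
  M <- t(B) %*% A
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  fitted <- B %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((fitted - A)^2))))
}

# Brute-force residue-level minimum heavy-atom distance scan.
oracle_pocket_scan <- function(struct, ligand_res_name, cutoff) {
  a <- struct$atoms
  lig <- which(a$res_name == ligand_res_name & a$element != "H")
  keys <- unique(a$res_key[!a$is_hetero & !a$is_water &
                             a$res_name != ligand_res_name])
  hits <- character()
  for (key in keys) {
    idx <- which(a$res_key == key & a$element != "H")
    dmin <- Inf
    for (i in idx) for (j in lig)
      dmin <- min(dmin, sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                               (a$z[i] - a$z[j])^2))
    if (dmin <= cutoff) hits <- c(hits, key)
  }
  hits
}

# Independent donor/acceptor table for the toy residues used in fixtures.
oracle_protein_polar <- list(
  donors = list(LYS = c("N", "NZ"), PHE = "N", VAL = "N", GLU = "N",
                THR = c("N", "OG1"), ILE = "N", TYR = c("N", "OH"),
                HIS = c("N", "ND1", "NE2"), ARG = c("N", "NE", "NH1", "NH2"),
                TRP = c("N", "NE1"), ALA = "N", SER = c("N", "OG"),
                LEU = "N", GLY = "N", PRO = character()),
  acceptors = list(LYS = "O", PHE = "O", VAL = "O", GLU = c("O", "OE1", "OE2"),
                   THR = c("O", "OG1"), ILE = "O", TYR = c("O", "OH"),
                   HIS = c("O", "ND1", "NE2"), ARG = "O", TRP = "O",
                   ALA = "O", SER = c("O", "OG"), LEU = "O", GLY = "O",
                   PRO = "O"))

# Brute-force double-loop H-bond enumeration over explicit polar tables.
# lig_polar: data.frame(name, donor, acceptor) for the ligand atoms.
oracle_hbond_scan <- function(struct, ligand_res_name, lig_polar, cutoff) {
  a <- struct$atoms
  don <- acc <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    rn <- a$res_name[i]
    if (rn %in% names(oracle_protein_polar$donors)) {
      don[i] <- a$name[i] %in% oracle_protein_polar$donors[[rn]]
      acc[i] <- a$name[i] %in% oracle_protein_polar$acceptors[[rn]]
    } else if (rn == "HOH" && a$element[i] == "O") {
      don[i] <- acc[i] <- TRUE
    } else if (rn == ligand_res_name) {
      k <- match(a$name[i], lig_polar$name)
      if (!is.na(k)) { don[i] <- lig_polar$donor[k]; acc[i] <- lig_polar$acceptor[k] }
    }
  }
  out <- NULL
  for (i in which(don)) for (j in which(acc)) {
    if (i == j || a$res_key[i] == a$res_key[j]) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d <= cutoff)
      out <- rbind(out, data.frame(donor_idx = i, acceptor_idx = j,
                                   distance = d))
  }
  out
}

# rigid motion helper: random rotation (QR of a seeded Gaussian) + shift
random_rigid_motion <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3) * 5)
}

transform_struct <- function(struct, rm) {
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")]) %*% t(rm$R)
  struct$atoms$x <- xyz[, 1] + rm$t[1]
  struct$atoms$y <- xyz[, 2] + rm$t[2]
  struct$atoms$z <- xyz[, 3] + rm$t[3]
  struct
}

transform_pose <- function(pose, rm) {
  mol <- pose$molecule
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(rm$R)
  mol$atoms$x <- xyz[, 1] + rm$t[1]
  mol$atoms$y <- xyz[, 2] + rm$t[2]
  mol$atoms$z <- xyz[, 3] + rm$t[3]
  ligand_pose(mol, pose$docking_score)
}

# Demo docked-pose set for pipeline tests: jittered copies of the
# reference ligand with deterministic scores.
make_demo_poses <- function(n = 5, seed = 5) {
  set.seed(seed)
  base <- reference_ligand_mol("LIG")
  lapply(seq_len(n), function(k) {
    mol <- base
    mol$title <- sprintf("demo_pose_%02d", k)
    mol$atoms$x <- mol$atoms$x + rnorm(nrow(mol$atoms), 0, 0.25)
    mol$atoms$y <- mol$atoms$y + rnorm(nrow(mol$atoms), 0, 0.25)
    mol$atoms$z <- mol$atoms$z + rnorm(nrow(mol$atoms), 0, 0.25)
    ligand_pose(mol, docking_score = 50 + 3 * k)
  })
}

extdata <- function(f) system.file("extdata", f, package = "agscreen")
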