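#' Define the ligand-binding pocket
#'
#' The pocket is the set of protein residues with at least one heavy atom
#' within `cutoff` (inclusive) of any heavy atom of the reference ligand.
#' The default cutoff of 6 A is the screen's published binding-site
#' definition.  Waters and hetero residues are excluded.
#'
#' @param receptor an `agstruct` containing the ligand.
#' @param ligand_res_name residue name of the bound reference ligand.
#' @param cutoff distance threshold, Angstrom.
#' @return a `pocket_definition`: list with `cutoff`, `ligand_res_name`
#'   and `residues` (data.frame res_key, chain, res_seq, insert, res_name,
#'   min_dist).
#' @export
define_pocket <- function(receptor, ligand_res_name, cutoff = 6.0) {
  stopifnot(cutoff >= 0)
  lig <- select_residue(receptor, ligand_res_name)
  lig <- lig[lig$element != "H", , drop = FALSE]
  at <- receptor$atoms
  prot <- at[!at$is_hetero & !at$is_water & at$element != "H" &
               at$res_name != ligand_res_name, , drop = FALSE]
  if (nrow(prot) == 0)
    return(structure(list(cutoff = cutoff, ligand_res_name = ligand_res_name,
                          residues = data.frame()),
                     class = "pocket_definition"))
  lxyz <- struct_coords(lig)
  pxyz <- struct_coords(prot)
  # min distance from each protein atom to any ligand heavy atom
  d2min <- rep(Inf, nrow(pxyz))
  for (k in seq_len(nrow(lxyz))) {
    d2 <- (pxyz[, 1] - lxyz[k, 1])^2 + (pxyz[, 2] - lxyz[k, 2])^2 +
      (pxyz[, 3] - lxyz[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  prot$min_dist <- sqrt(d2min)
  agg <- tapply(prot$min_dist, prot$res_key, min)
  keys <- names(agg)[agg <= cutoff]
  first <- prot[!duplicated(prot$res_key), , drop = FALSE]
  sel <- first[first$res_key %in% keys, , drop = FALSE]
  resdf <- data.frame(res_key = sel$res_key, chain = sel$chain,
                      res_seq = sel$res_seq, insert = sel$insert,
                      res_name = sel$res_name,
                      min_dist = as.numeric(agg[sel$res_key]),
                      stringsAsFactors = FALSE)
  resdf <- resdf[order(match(resdf$res_key, at$res_key)), , drop = FALSE]
  rownames(resdf) <- NULL
  structure(list(cutoff = cutoff, ligand_res_name = ligand_res_name,
                 residues = resdf),
            class = "pocket_definition")
}

#' @export
print.pocket_definition <- function(x, ...) {
  cat(sprintf("<pocket: %d residues within %.1f A of %s>\n",
              nrow(x$residues), x$cutoff, x$ligand_res_name))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation + translation mapping paired atoms of `struct_b` onto
#' `struct_a`, computed by the Kabsch SVD construction with the
#' determinant correction, so a proper rotation (no reflection) is always
#' returned.
#'
#' @param struct_a,struct_b `agstruct` objects.
#' @param pairing data.frame with columns `key_a`, `key_b` (residue keys
#'   as in `residues()`) and optionally `atom` (default `"CA"`): which
#'   atom of each paired residue enters the fit.  Alternatively a list
#'   with elements `xyz_a`, `xyz_b` (n x 3 matrices) for direct
#'   coordinate pairing.
#' @return a `superposition`: list with `rotation` (3x3), `translation`
#'   (length 3; the fitted map is `x %*% t(R) + t`), `rmsd`, `n_pairs`
#'   and the matrices used.
#' @export
superpose <- function(struct_a, struct_b, pairing) {
  if (is.data.frame(pairing)) {
    atom <- if (is.null(pairing$atom)) rep("CA", nrow(pairing)) else pairing$atom
    pick <- function(s, key, at_name) {
      hit <- s$atoms[s$atoms$res_key == key & s$atoms$name == at_name, ,
                     drop = FALSE]
      if (nrow(hit) != 1)
        stop("pairing atom not found: ", key, "/", at_name, call. = FALSE)
      c(hit$x, hit$y, hit$z)
    }
    xa <- t(vapply(seq_len(nrow(pairing)), function(k)
      pick(struct_a, pairing$key_a[k], atom[k]), numeric(3)))
    xb <- t(vapply(seq_len(nrow(pairing)), function(k)
      pick(struct_b, pairing$key_b[k], atom[k]), numeric(3)))
  } else {
    xa <- pairing$xyz_a; xb <- pairing$xyz_b
  }
  if (nrow(xa) < 3) stop("need at least 3 paired atoms", call. = FALSE)
  ca <- colMeans(xa); cb <- colMeans(xb)
  A <- sweep(xa, 2, ca); B <- sweep(xb, 2, cb)
  sv <- svd(crossprod(B, A))          # H = B^T A
  if (sv$d[2] < 1e-12)
    stop("paired atoms are collinear; superposition is degenerate",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ca - as.vector(R %*% cb)
  fitted <- B %*% t(R)                # = (xb - cb) R^T
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_pairs = nrow(xa), xyz_a = xa, xyz_b = xb),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d pairs, rmsd %.4f A>\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a [superpose()] result.
#' @param xyz n x 3 matrix in the frame of `struct_b`.
#' @return n x 3 matrix in the frame of `struct_a`.
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(xyz %*% t(sup$rotation), 2, -sup$translation)
}

#' Spatially matched residue differences between two pockets
#'
#' After superposing structure B onto structure A, each pocket residue of
#' A is matched to the nearest Calpha of B within `match_cutoff`
#' (greedy nearest-first; every B residue used at most once).  Pairs whose
#' residue names differ are substitutions — the computation behind
#' transferring pocket substitutions between homologous receptors.
#'
#' @param struct_a,struct_b `agstruct` objects.
#' @param pocket_a a [define_pocket()] result on `struct_a`.
#' @param sup a [superpose()] result mapping B onto A.
#' @param match_cutoff maximum Calpha-Calpha distance for a match,
#'   Angstrom.
#' @return data.frame with one row per pocket residue of A: key_a,
#'   res_name_a, key_b, res_name_b, ca_dist, same_identity, matched.
#' @export
diff_pocket <- function(struct_a, struct_b, pocket_a, sup,
                        match_cutoff = 2.0) {
  ca_of <- function(s) {
    ca <- s$atoms[s$atoms$name == "CA" & !s$atoms$is_water, , drop = FALSE]
    ca[!duplicated(ca$res_key), , drop = FALSE]
  }
  ca_a <- ca_of(struct_a); ca_b <- ca_of(struct_b)
  ca_a <- ca_a[ca_a$res_key %in% pocket_a$residues$res_key, , drop = FALSE]
  if (nrow(ca_a) == 0) return(data.frame())
  xb <- apply_superposition(sup, struct_coords(ca_b))
  xa <- struct_coords(ca_a)
  dmat <- sqrt(pmax(outer(rowSums(xa^2), rep(1, nrow(xb))) +
                      outer(rep(1, nrow(xa)), rowSums(xb^2)) -
                      2 * xa %*% t(xb), 0))
  out <- data.frame(key_a = ca_a$res_key, res_name_a = ca_a$res_name,
                    key_b = NA_character_, res_name_b = NA_character_,
                    ca_dist = NA_real_, same_identity = NA,
                    matched = FALSE, stringsAsFactors = FALSE)
  used_b <- rep(FALSE, nrow(xb))
  repeat {
    open_a <- which(!out$matched)
    open_b <- which(!used_b)
    if (!length(open_a) || !length(open_b)) break
    sub <- dmat[open_a, open_b, drop = FALSE]
    k <- which.min(sub)
    if (sub[k] > match_cutoff) break
    ia <- open_a[(k - 1) %% length(open_a) + 1]
    ib <- open_b[(k - 1) %/% length(open_a) + 1]
    out$key_b[ia] <- ca_b$res_key[ib]
    out$res_name_b[ia] <- ca_b$res_name[ib]
    out$ca_dist[ia] <- dmat[ia, ib]
    out$same_identity[ia] <- ca_a$res_name[ia] == ca_b$res_name[ib]
    out$matched[ia] <- TRUE
    used_b[ib] <- TRUE
  }
  out
}

#' Second-shell residues around a pocket
#'
#' Protein residues outside the pocket with a heavy atom within
#' `shell_cutoff` (inclusive) of any pocket-residue heavy atom.  Captures
#' design-relevant residues beyond the primary contact shell, e.g. chains
#' of interacting residues along the beta sheet.
#'
#' @param struct an `agstruct`.
#' @param pocket a [define_pocket()] result.
#' @param shell_cutoff distance threshold, Angstrom.
#' @return data.frame like `pocket$residues` (res_key, chain, res_seq,
#'   insert, res_name, min_dist).
#' @export
second_shell <- function(struct, pocket, shell_cutoff = 4.5) {
  stopifnot(shell_cutoff >= 0)
  at <- struct$atoms
  prot <- at[!at$is_hetero & !at$is_water & at$element != "H", , drop = FALSE]
  in_pocket <- prot$res_key %in% pocket$residues$res_key
  pk <- prot[in_pocket, , drop = FALSE]
  cand <- prot[!in_pocket, , drop = FALSE]
  if (nrow(pk) == 0 || nrow(cand) == 0 || shell_cutoff == 0)
    return(pk[0, c("res_key", "chain", "res_seq", "insert", "res_name"),
              drop = FALSE])
  pxyz <- struct_coords(pk); cxyz <- struct_coords(cand)
  d2min <- rep(Inf, nrow(cxyz))
  for (k in seq_len(nrow(pxyz))) {
    d2 <- (cxyz[, 1] - pxyz[k, 1])^2 + (cxyz[, 2] - pxyz[k, 2])^2 +
      (cxyz[, 3] - pxyz[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  cand$min_dist <- sqrt(d2min)
  agg <- tapply(cand$min_dist, cand$res_key, min)
  keys <- names(agg)[agg <= shell_cutoff]
  first <- cand[!duplicated(cand$res_key), , drop = FALSE]
  sel <- first[first$res_key %in% keys, , drop = FALSE]
  out <- data.frame(res_key = sel$res_key, chain = sel$chain,
                    res_seq = sel$res_seq, insert = sel$insert,
                    res_name = sel$res_name,
                    min_dist = as.numeric(agg[sel$res_key]),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$res_key, at$res_key)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
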