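# minimal two-partner fixture: a ligand carbonyl O near a backbone N
hb_fixture <- function(no_dist) {
  lig <- data.frame(record = "HETATM", name = c("C1", "O1"), res_name = "LIG",
                    chain = "A", res_seq = 900, insert = "",
                    x = c(-1.4, 0), y = 0, z = 0, element = c("C", "O"))
  res <- data.frame(record = "ATOM", name = c("N", "CA", "C", "O"),
                    res_name = "ALA", chain = "A", res_seq = 5, insert = "",
                    x = c(no_dist, no_dist + 1.4, no_dist + 2.1,
                          no_dist + 3.2),
                    y = c(0, 0.5, 1.6, 2.6), z = 0,
                    element = c("N", "C", "C", "O"))
  receptor_structure(rbind(lig, res))
}

test_that("heavy-atom H-bond criterion is a distance cutoff", {
  hb <- find_hbonds(hb_fixture(2.9), "LIG")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_atom, "N")
  expect_equal(hb$acceptor_atom, "O1")
  expect_equal(hb$distance, 2.9)
  expect_true(is.na(hb$angle))              # no hydrogens present
  expect_equal(nrow(find_hbonds(hb_fixture(3.6), "LIG")), 0)
  # cutoff monotonicity: larger cutoff yields a superset
  hb4 <- find_hbonds(hb_fixture(3.6), "LIG", cutoff = 4.0)
  expect_equal(nrow(hb4), 1)
})

test_that("H-bond detection equals brute-force enumeration on toy complexes", {
  lig_polar <- data.frame(name = c("C1", "O1", "C2", "C3", "C6", "C7",
                                   "O3", "O4"),
                          donor = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                                    FALSE, TRUE),
                          acceptor = c(FALSE, TRUE, FALSE, FALSE, FALSE,
                                       FALSE, TRUE, TRUE))
  for (seed in c(2, 9)) {
    tc <- make_toy_complex(seed = seed, jitter_sigma = 0.25)
    got <- find_hbonds(tc, "ABA", ligand_mol = reference_ligand_mol(),
                       cutoff = 3.5)
    want <- oracle_hbond_scan(tc, "ABA", lig_polar, 3.5)
    got_pairs <- paste(got$donor_idx, got$acceptor_idx)
    want_pairs <- if (is.null(want)) character() else
      paste(want$donor_idx, want$acceptor_idx)
    expect_setequal(got_pairs, want_pairs)
  }
})

test_that("water bridges: construction, removal, brute-force agreement", {
  lig <- data.frame(record = "HETATM", name = c("C1", "O1"), res_name = "LIG",
                    chain = "A", res_seq = 900, insert = "",
                    x = c(-1.4, 0), y = 0, z = 0, element = c("C", "O"))
  res <- data.frame(record = "ATOM", name = c("N", "CA", "C", "O"),
                    res_name = "ASN", chain = "A", res_seq = 196, insert = "",
                    x = c(5.6, 6.4, 7.6, 8.4), y = c(0, 1, 1, 2), z = 0,
                    element = c("N", "C", "C", "O"))
  wat <- data.frame(record = "HETATM", name = "O", res_name = "HOH",
                    chain = "S", res_seq = 601, insert = "",
                    x = 2.8, y = 0, z = 0, element = "O")
  s <- receptor_structure(rbind(lig, res, wat))
  br <- find_water_bridges(s, "LIG")       # water 2.8 from O1 and from N
  expect_equal(nrow(br), 1)
  expect_equal(br$ligand_atom, "O1")
  expect_equal(br$protein_atom, "N")
  s_dry <- receptor_structure(rbind(lig, res))
  expect_equal(nrow(find_water_bridges(s_dry, "LIG")), 0)
  # multi-water toy complex vs direct enumeration
  tc <- make_toy_complex(seed = 5, n_waters = 6)
  br2 <- find_water_bridges(tc, "ABA", ligand_mol = reference_ligand_mol())
  a <- tc$atoms
  typ <- agscreen:::.ag_complex_hbond_typing(tc, "ABA",
                                             reference_ligand_mol())
  polar <- typ$donor | typ$acceptor
  n_want <- 0L
  for (w in which(a$is_water)) for (i in which(a$res_name == "ABA" & polar))
    for (j in which(!a$is_water & polar &
                      a$res_name %in% agscreen:::.ag_standard_residues)) {
      dw1 <- sqrt(sum((c(a$x[w], a$y[w], a$z[w]) -
                         c(a$x[i], a$y[i], a$z[i]))^2))
      dw2 <- sqrt(sum((c(a$x[w], a$y[w], a$z[w]) -
                         c(a$x[j], a$y[j], a$z[j]))^2))
      if (dw1 <= 3.5 && dw2 <= 3.5) n_want <- n_want + 1L
    }
  expect_equal(nrow(br2), n_want)
})

test_that("Trp-lock motif matches exactly once and is distance-sensitive", {
  tc <- make_toy_complex(seed = 3)
  pat <- trp_lock_pattern(ligand_res_name = "ABA")
  m <- match_motif(tc, pat)
  expect_equal(nrow(m), 1)
  expect_equal(m$water_res_seq, attr(tc, "lock_water_res_seq"))
  expect_equal(m$latch_n_res_seq, 145)
  expect_equal(m$gate_o_res_seq, 117)
  expect_equal(m$trp_ne1_res_seq, 385)
  # perturb the lock water by +3 A: no match
  tc2 <- tc
  w <- which(tc2$atoms$res_seq == m$water_res_seq & tc2$atoms$is_water)
  tc2$atoms$x[w] <- tc2$atoms$x[w] + 3
  expect_equal(nrow(match_motif(tc2, pat)), 0)
  # no-lock complex: slot resolvable check
  tc3 <- make_toy_complex(seed = 3, with_trp_lock = FALSE, n_waters = 0)
  expect_error(match_motif(tc3, pat), "no candidate atoms")
})

test_that("with competing waters only the satisfying one matches", {
  tc <- make_toy_complex(seed = 4, n_waters = 5)   # bulk waters far away
  pat <- trp_lock_pattern(ligand_res_name = "ABA")
  m <- match_motif(tc, pat)
  expect_equal(nrow(m), 1)
  # exhaustive check over every water candidate
  a <- tc$atoms
  lock_xyz <- function(i) c(a$x[i], a$y[i], a$z[i])
  anchors <- list(
    which(a$res_name == "ABA" & a$name == "O1"),
    which(a$res_seq == 145 & a$name == "N"),
    which(a$res_seq == 117 & a$name == "O"),
    which(a$res_seq == 385 & a$name == "NE1"))
  sat <- integer()
  for (w in which(a$is_water))
    if (all(vapply(anchors, function(i)
      sqrt(sum((lock_xyz(w) - lock_xyz(i))^2)) <= 3.5, TRUE)))
      sat <- c(sat, a$res_seq[w])
  expect_equal(m$water_res_seq, sat)
})

test_that("hydrophobic contacts: cutoffs, counts and ethyl > methyl", {
  lig <- data.frame(record = "HETATM", name = c("C1", "C2"), res_name = "LIG",
                    chain = "A", res_seq = 900, insert = "",
                    x = c(0, 1.5), y = 0, z = 0, element = "C")
  leu <- data.frame(record = "ATOM", name = c("CA", "CB", "CG", "CD1"),
                    res_name = "LEU", chain = "A", res_seq = 87, insert = "",
                    x = c(8, 6.8, 6.2, 5.5), y = 0, z = 0, element = "C")
  s <- receptor_structure(rbind(lig, leu))
  ct <- hydrophobic_contacts(s, "LIG", residue_set = 87, cutoff = 4.5)
  expect_equal(ct$n_contacts, 1)            # C2..CD1 at 4.0
  expect_equal(ct$contacts$ligand_atom, "C2")
  expect_equal(ct$contacts$res_atom, "CD1")
  expect_equal(hydrophobic_contacts(s, "LIG", 87, cutoff = 3.0)$n_contacts, 0)
  # ethyl extension adds a carbon closer to the tunnel: strictly more contacts
  lig_et <- rbind(lig, data.frame(record = "HETATM", name = "C3",
                                  res_name = "LIG", chain = "A", res_seq = 900,
                                  insert = "", x = 3.0, y = 0, z = 0,
                                  element = "C"))
  s_et <- receptor_structure(rbind(lig_et, leu))
  ct_et <- hydrophobic_contacts(s_et, "LIG", 87, cutoff = 4.5)
  expect_gt(ct_et$n_contacts, ct$n_contacts)
  # brute-force recount
  a <- s_et$atoms
  n_want <- 0L
  for (i in which(a$res_name == "LIG" & a$element %in% c("C", "S")))
    for (j in which(a$res_name == "LEU" & a$element %in% c("C", "S")))
      if (sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                 (a$z[i] - a$z[j])^2) <= 4.5) n_want <- n_want + 1L
  expect_equal(ct_et$n_contacts, n_want)
})

test_that("interaction detections are rigid-motion invariant", {
  tc <- make_toy_complex(seed = 7)
  rm <- random_rigid_motion(55)
  tcm <- transform_struct(tc, rm)
  h0 <- find_hbonds(tc, "ABA", ligand_mol = reference_ligand_mol())
  h1 <- find_hbonds(tcm, "ABA", ligand_mol = reference_ligand_mol())
  expect_equal(h1[, c("donor_idx", "acceptor_idx")],
               h0[, c("donor_idx", "acceptor_idx")])
  expect_equal(h1$distance, h0$distance, tolerance = 1e-9)
  expect_equal(nrow(match_motif(tcm, trp_lock_pattern("ABA"))),
               nrow(match_motif(tc, trp_lock_pattern("ABA"))))
  c0 <- hydrophobic_contacts(tc, "ABA")
  c1 <- hydrophobic_contacts(tcm, "ABA")
  expect_equal(c1$n_contacts, c0$n_contacts)
})
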