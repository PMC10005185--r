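test_that("pocket boundary is inclusive at the 6 A cutoff", {
  lig <- data.frame(record = "HETATM", name = "C1", res_name = "LIG",
                    chain = "A", res_seq = 900, insert = "",
                    x = 0, y = 0, z = 0, element = "C")
  near <- data.frame(record = "ATOM", name = c("CA", "CB"), res_name = "ALA",
                     chain = "A", res_seq = 10, insert = "",
                     x = c(7.2, 5.9), y = 0, z = 0, element = "C")
  far <- data.frame(record = "ATOM", name = c("CA", "CB"), res_name = "ALA",
                    chain = "A", res_seq = 11, insert = "",
                    x = c(-7.5, -6.1), y = 0, z = 0, element = "C")
  exact <- data.frame(record = "ATOM", name = "CA", res_name = "GLY",
                      chain = "A", res_seq = 12, insert = "",
                      x = 0, y = 6.0, z = 0, element = "C")
  s <- receptor_structure(rbind(lig, near, far, exact))
  p <- define_pocket(s, "LIG", 6.0)
  expect_setequal(p$residues$res_seq, c(10, 12))   # 5.9 in, 6.0 in, 6.1 out
  expect_equal(nrow(define_pocket(s, "LIG", 0)$residues), 0)
})

test_that("pocket equals brute-force scan and is monotone in cutoff", {
  for (seed in 1:5) {
    tc <- make_toy_complex(seed = seed, n_pocket_residues = 6,
                           n_outer_residues = 5, n_waters = 2,
                           jitter_sigma = 0.4)
    for (cutoff in c(4.5, 6.0, 8.0)) {
      p <- define_pocket(tc, "ABA", cutoff)
      expect_setequal(p$residues$res_key, oracle_pocket_scan(tc, "ABA", cutoff))
    }
    p1 <- define_pocket(tc, "ABA", 4.5)$residues$res_key
    p2 <- define_pocket(tc, "ABA", 6.0)$residues$res_key
    expect_true(all(p1 %in% p2))
  }
})

test_that("superposition: identity, exact recovery, reflection never returned", {
  tc <- make_toy_complex(seed = 6)
  keys <- residues(tc)$res_key[residues(tc)$res_name %in%
                                 agscreen:::.ag_standard_residues]
  pairing <- data.frame(key_a = keys, key_b = keys)
  sup <- superpose(tc, tc, pairing)
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sup$translation, c(0, 0, 0), tolerance = 1e-10)
  rm <- random_rigid_motion(41)
  tcb <- transform_struct(tc, rm)
  sup2 <- superpose(tc, tcb, pairing)
  expect_lt(sup2$rmsd, 1e-8)
  expect_equal(sup2$rotation, t(rm$R), tolerance = 1e-8)
  expect_equal(det(sup2$rotation), 1, tolerance = 1e-6)
})

test_that("noisy superposition matches the quaternion-method oracle", {
  tc <- make_toy_complex(seed = 8)
  keys <- residues(tc)$res_key[residues(tc)$res_name %in%
                                 agscreen:::.ag_standard_residues]
  pairing <- data.frame(key_a = keys, key_b = keys)
  rm <- random_rigid_motion(42)
  tcb <- transform_struct(tc, rm)
  set.seed(77)
  tcb$atoms$x <- tcb$atoms$x + rnorm(nrow(tcb$atoms), 0, 0.3)
  tcb$atoms$y <- tcb$atoms$y + rnorm(nrow(tcb$atoms), 0, 0.3)
  tcb$atoms$z <- tcb$atoms$z + rnorm(nrow(tcb$atoms), 0, 0.3)
  sup <- superpose(tc, tcb, pairing)
  orc <- oracle_quaternion_superpose(sup$xyz_a, sup$xyz_b)
  expect_equal(sup$rmsd, orc$rmsd, tolerance = 1e-6 / orc$rmsd)
  expect_equal(sup$rotation, orc$rotation, tolerance = 1e-6)
  # symmetry: fitting A onto B gives the same rmsd
  sup_rev <- superpose(tcb, tc, data.frame(key_a = keys, key_b = keys))
  expect_equal(sup_rev$rmsd, sup$rmsd, tolerance = 1e-9)
})

test_that("degenerate superposition inputs are rejected", {
  xa <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_error(superpose(NULL, NULL, list(xyz_a = xa, xyz_b = xa)),
               "at least 3")
  col <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), 4, 3, byrow = TRUE)
  expect_error(superpose(NULL, NULL, list(xyz_a = col, xyz_b = col)),
               "collinear")
})

test_that("pocket diff: identity matching, 5-substitution pair, order invariance", {
  tc <- make_toy_complex(seed = 10, n_pocket_residues = 11)
  pocket <- define_pocket(tc, "ABA", 6.0)
  keys <- residues(tc)$res_key[residues(tc)$res_name %in%
                                 agscreen:::.ag_standard_residues]
  pairing <- data.frame(key_a = keys, key_b = keys)
  d0 <- diff_pocket(tc, tc, pocket, superpose(tc, tc, pairing))
  expect_true(all(d0$matched))
  expect_true(all(d0$same_identity))
  expect_equal(d0$key_b, d0$key_a)
  # engineered five-substitution variant
  preset <- cspyl1_5m_preset()
  pair <- make_mutant_pair(tc, preset[preset$res_seq != 168, ])  # 112,135,137,153 in pocket
  subs4 <- preset$res_seq[preset$res_seq != 168]
  d <- diff_pocket(pair$a, pair$b, pocket, superpose(pair$a, pair$b, pairing))
  expect_true(all(d$matched))
  got_subs <- d$key_a[!d$same_identity]
  expect_setequal(got_subs, paste0("A|", subs4, "|"))
  # full preset incl. the out-of-pocket 168 via an extended outer residue
  tc2 <- make_toy_complex(seed = 10, n_pocket_residues = 11,
                          n_outer_residues = 4)
  pair2 <- make_mutant_pair(tc2, preset)
  all_keys <- residues(tc2)$res_key[residues(tc2)$res_name %in%
                                      agscreen:::.ag_standard_residues]
  allres <- define_pocket(tc2, "ABA", 30)   # generous: every protein residue
  d2 <- diff_pocket(pair2$a, pair2$b, allres,
                    superpose(pair2$a, pair2$b,
                              data.frame(key_a = all_keys, key_b = all_keys)))
  expect_equal(sum(!d2$same_identity), 5)
  expect_setequal(d2$key_a[!d2$same_identity], paste0("A|", preset$res_seq, "|"))
  # shuffled residue order in B leaves the diff unchanged
  b_shuf <- pair$b
  res_blocks <- split(seq_len(nrow(b_shuf$atoms)), b_shuf$atoms$res_key)
  set.seed(3)
  b_shuf$atoms <- b_shuf$atoms[unlist(res_blocks[sample(length(res_blocks))]), ]
  b_shuf <- receptor_structure(b_shuf$atoms[, c("record", "name", "res_name",
                                                "chain", "res_seq", "insert",
                                                "x", "y", "z", "element")])
  d_shuf <- diff_pocket(pair$a, b_shuf, pocket,
                        superpose(pair$a, b_shuf, pairing))
  expect_equal(d_shuf[order(d_shuf$key_a), c("key_a", "key_b", "same_identity")],
               d[order(d$key_a), c("key_a", "key_b", "same_identity")],
               ignore_attr = TRUE)
})

test_that("second shell: brute-force agreement and edge cases", {
  tc <- make_toy_complex(seed = 12, n_pocket_residues = 7,
                         n_outer_residues = 6, jitter_sigma = 0.3)
  pocket <- define_pocket(tc, "ABA", 6.0)
  sh <- second_shell(tc, pocket, 4.5)
  # independent scan
  a <- tc$atoms
  pk_atoms <- which(a$res_key %in% pocket$residues$res_key & a$element != "H")
  want <- character()
  for (key in setdiff(unique(a$res_key[!a$is_hetero & !a$is_water]),
                      pocket$residues$res_key)) {
    idx <- which(a$res_key == key & a$element != "H")
    dmin <- Inf
    for (i in idx) for (j in pk_atoms)
      dmin <- min(dmin, sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                               (a$z[i] - a$z[j])^2))
    if (dmin <= 4.5) want <- c(want, key)
  }
  expect_setequal(sh$res_key, want)
  expect_equal(nrow(second_shell(tc, pocket, 0)), 0)
  expect_false(any(sh$res_key %in% pocket$residues$res_key))
})

test_that("a residue adjacent at 4.0 A enters the default second shell", {
  lig <- data.frame(record = "HETATM", name = "C1", res_name = "LIG",
                    chain = "A", res_seq = 900, insert = "",
                    x = 0, y = 0, z = 0, element = "C")
  pocket_res <- data.frame(record = "ATOM", name = "CA", res_name = "ALA",
                           chain = "A", res_seq = 1, insert = "",
                           x = 5, y = 0, z = 0, element = "C")
  neighbor <- data.frame(record = "ATOM", name = "CA", res_name = "SER",
                         chain = "A", res_seq = 2, insert = "",
                         x = 9, y = 0, z = 0, element = "C")
  s <- receptor_structure(rbind(lig, pocket_res, neighbor))
  p <- define_pocket(s, "LIG", 6.0)
  expect_equal(p$residues$res_seq, 1)
  expect_equal(second_shell(s, p, 4.5)$res_seq, 2)
})
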