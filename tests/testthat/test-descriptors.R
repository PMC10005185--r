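test_that("default descriptor construction anchors and constants", {
  tc <- make_toy_complex(seed = 2)
  sph <- build_descriptors(tc, "ABA")
  expect_equal(vapply(sph, `[[`, "", "name"),
               c("keto_O", "carboxylate", "methyl", "pocket_centroid"))
  expect_equal(vapply(sph, `[[`, 0, "radius"), c(1.5, 2.8, 1.4, 3.5))
  expect_equal(vapply(sph, `[[`, "", "required_property"),
               c("hba", "hba", "hydrophobic", "hydrophobic"))
  lig <- select_residue(tc, "ABA")
  expect_equal(sph[[1]]$center,
               as.numeric(lig[lig$name == "O1", c("x", "y", "z")]))
  expect_equal(sph[[2]]$center,
               colMeans(struct_coords(lig[lig$name %in% c("O3", "O4"), ])),
               ignore_attr = TRUE)
  # YAML config route builds the identical spheres
  sph2 <- load_descriptor_config(extdata("descriptors.yaml"), tc, "ABA")
  for (k in 1:4) {
    expect_equal(sph2[[k]]$center, sph[[k]]$center)
    expect_equal(sph2[[k]]$radius, sph[[k]]$radius)
  }
})

test_that("two-residue centroid of symmetric side chains sits at midpoint", {
  res1 <- data.frame(record = "ATOM", name = c("CA", "CB"), res_name = "ALA",
                     chain = "A", res_seq = 1, insert = "",
                     x = c(-3, -1), y = 0, z = 0, element = "C")
  res2 <- data.frame(record = "ATOM", name = c("CA", "CB"), res_name = "ALA",
                     chain = "A", res_seq = 2, insert = "",
                     x = c(3, 1), y = 0, z = 0, element = "C")
  lig <- data.frame(record = "HETATM", name = c("O1", "O3", "O4", "C6"),
                    res_name = "ABA", chain = "A", res_seq = 501, insert = "",
                    x = c(0, 1, -1, 0.5), y = 5, z = 0,
                    element = c("O", "O", "O", "C"))
  s <- receptor_structure(rbind(res1, res2, lig))
  sph <- build_descriptors(s, "ABA",
                           anchor_spec = list(pocket_residues = c(1, 2)))
  expect_equal(sph[[4]]$center, c(0, 0, 0))  # CB centroid (side chains only)
})

test_that("grid occupancy matches the closed-form lens fraction", {
  s <- pharmacophore_sphere("t", c(1.3, -0.7, 2.1), 1.5, "hba")
  r_o <- vdw_radius("O")
  for (d in c(0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0)) {
    mol <- molecule(data.frame(element = "O", name = "O1",
                               x = s$center[1] + d, y = s$center[2],
                               z = s$center[3]))
    got <- sphere_occupancy(s, ligand_pose(mol), spacing = 0.2)
    want <- 100 * oracle_lens_fraction(1.5, r_o, d)
    expect_lt(abs(got - want), 1)   # within one percentage point
  }
})

test_that("edge cases: no qualifying atom, containment, property gating", {
  s <- pharmacophore_sphere("t", c(0, 0, 0), 1.4, "hydrophobic")
  far <- molecule(data.frame(element = "C", name = "C1", x = 9, y = 0, z = 0))
  expect_equal(sphere_occupancy(s, ligand_pose(far)), 0)
  conc <- molecule(data.frame(element = "C", name = "C1", x = 0, y = 0, z = 0))
  expect_equal(sphere_occupancy(s, ligand_pose(conc)), 100)  # vdW 1.70 >= 1.4
  # an oxygen at the same spot does not qualify for a hydrophobic sphere
  o_at <- molecule(data.frame(element = "O", name = "O1", x = 0, y = 0, z = 0))
  expect_equal(sphere_occupancy(s, ligand_pose(o_at)), 0)
  expect_gt(sphere_occupancy(pharmacophore_sphere("t", c(0, 0, 0), 1.4, "any"),
                             ligand_pose(o_at)), 99)
})

test_that("occupancy is monotone in added atoms and stable under shrink", {
  s <- pharmacophore_sphere("t", c(0, 0, 0), 2.8, "hba")
  one <- molecule(data.frame(element = "O", name = "O1", x = 1.2, y = 0, z = 0))
  two <- molecule(data.frame(element = c("O", "O"), name = c("O1", "O2"),
                             x = c(1.2, -1.0), y = c(0, 0.5), z = 0))
  expect_gte(sphere_occupancy(s, ligand_pose(two)),
             sphere_occupancy(s, ligand_pose(one)))
  # full coverage stays 100 as the sphere shrinks around the atom
  for (rad in c(1.5, 1.0, 0.5)) {
    sh <- pharmacophore_sphere("t", c(0, 0, 0), rad, "hba")
    cov <- molecule(data.frame(element = "O", name = "O1", x = 0, y = 0, z = 0))
    expect_equal(sphere_occupancy(sh, ligand_pose(cov)), 100)
  }
})

test_that("grid estimate converges to the analytic value as spacing shrinks", {
  s <- pharmacophore_sphere("t", c(0, 0, 0), 1.5, "hba")
  dists <- seq(0, 1.5 + vdw_radius("O"), length.out = 25)
  panel_err <- function(sp) {
    max(vapply(dists, function(d) {
      mol <- molecule(data.frame(element = "O", name = "O1",
                                 x = d, y = 0, z = 0))
      abs(sphere_occupancy(s, ligand_pose(mol), spacing = sp) -
            100 * oracle_lens_fraction(1.5, vdw_radius("O"), d))
    }, 0))
  }
  errs <- vapply(c(0.4, 0.2, 0.1), panel_err, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("Monte Carlo sampler agrees with the grid and is seed-stable", {
  s <- pharmacophore_sphere("t", c(0.4, 1.1, -0.3), 1.5, "hba")
  pose <- make_pose_with_occupancy(s, 42, "O")
  g <- sphere_occupancy(s, pose, spacing = 0.2)
  m1 <- sphere_occupancy(s, pose, sampler = "mc", points = 2e5, seed = 11)
  m2 <- sphere_occupancy(s, pose, sampler = "mc", points = 2e5, seed = 11)
  expect_identical(m1, m2)
  expect_equal(m1, g, tolerance = 0.5 / g)
  expect_error(sphere_occupancy(s, pose, sampler = "mc"), "seed")
})

test_that("scoring is deterministic and rigid-motion invariant", {
  tc <- make_toy_complex(seed = 4)
  sph <- build_descriptors(tc, "ABA")
  poses <- make_demo_poses(3, seed = 8)
  t1 <- score_poses(poses, sph)
  t2 <- score_poses(poses, sph)
  expect_identical(t1, t2)
  rm <- random_rigid_motion(17)
  sph_m <- lapply(sph, function(x) {
    x$center <- as.numeric(rm$R %*% x$center + rm$t); x })
  poses_m <- lapply(poses, transform_pose, rm = rm)
  t3 <- score_poses(poses_m, sph_m)
  occ_cols <- grep("^occ_", names(t1))
  expect_equal(as.matrix(t3[, occ_cols]), as.matrix(t1[, occ_cols]),
               tolerance = 0.02)
})
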