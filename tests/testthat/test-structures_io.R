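test_that("toy PDB fixture parses: residues, altlocs, waters, elements", {
  s <- read_pdb(extdata("toy3.pdb"))
  r <- residues(s)
  expect_equal(nrow(r), 3)
  expect_equal(r$res_name, c("ALA", "GLY", "HOH"))
  # altloc A (occupancy 0.6) retained, B dropped
  ala_n <- s$atoms[s$atoms$res_seq == 1 & s$atoms$name == "N", ]
  expect_equal(nrow(ala_n), 1)
  expect_equal(ala_n$x, 11.104)
  # insertion code preserved in residue key
  expect_true("A|2|A" %in% s$atoms$res_key)
  # element inference and water flagging
  expect_equal(s$atoms$element[s$atoms$name == "CB"], "C")
  expect_true(all(s$atoms$is_water[s$atoms$res_name == "HOH"]))
  expect_false(any(s$atoms$is_water[s$atoms$res_name != "HOH"]))
})

test_that("altloc policy 'first' keeps the first-encountered altloc", {
  s <- read_pdb(extdata("toy3.pdb"), altloc_policy = "first")
  expect_equal(s$atoms$x[s$atoms$name == "N" & s$atoms$res_seq == 1], 11.104)
  # reverse the occupancies so B is higher: policy choice becomes visible
  lines <- readLines(extdata("toy3.pdb"))
  lines <- sub("0.60 10.00           N", "0.30 10.00           N", lines)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  s_hi <- read_pdb(tf)                       # highest occupancy: B (0.40)
  expect_equal(s_hi$atoms$x[s_hi$atoms$name == "N" &
                              s_hi$atoms$res_seq == 1], 11.204)
  s_first <- read_pdb(tf, altloc_policy = "first")
  expect_equal(s_first$atoms$x[s_first$atoms$name == "N" &
                                 s_first$atoms$res_seq == 1], 11.104)
})

test_that("malformed PDB coordinates raise an error naming the line", {
  lines <- readLines(extdata("toy3.pdb"))
  lines[4] <- paste0(substr(lines[4], 1, 30), "  xx.xxx",
                     substr(lines[4], 39, nchar(lines[4])))
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  expect_error(read_pdb(tf), "line 4")
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", tf2)
  expect_error(read_pdb(tf2), "empty|no ATOM")
})

test_that("PDB round trip preserves coordinates, identities and order", {
  s <- make_toy_complex(seed = 3)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tf)
  s2 <- read_pdb(tf)
  expect_equal(residues(s2)$res_name, residues(s)$res_name)
  expect_equal(residues(s2)$res_seq, residues(s)$res_seq)
  heavy <- s$atoms$element != "H"
  expect_equal(struct_coords(s2)[heavy, ], struct_coords(s)[heavy, ],
               tolerance = 1.1e-3, ignore_attr = TRUE)
})

test_that("SDF read: score tag, charges, and optional-tag contract", {
  sdf <- c("mol1", "  fixture", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.5000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
           "    2.5000    1.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0", "  2  3  2  0",
           "M  CHG  1   2   1", "M  END",
           "> <CHEMPLP>", "57.3", "", "$$$$",
           "mol2", "  fixture", "",
           "  1  0  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "M  END", "$$$$")
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, tf)
  poses <- read_sdf(tf)
  expect_length(poses, 2)
  expect_equal(poses[[1]]$docking_score, 57.3)
  expect_equal(poses[[1]]$molecule$atoms$charge, c(0L, 1L, 0L))
  expect_equal(poses[[1]]$molecule$title, "mol1")
  expect_true(is.na(poses[[2]]$docking_score))
})

test_that("SDF round trip is identical at 4 decimals incl. charges and tags", {
  lib <- make_library(n = 8, seed = 2)
  p0 <- lib$poses
  p0[[1]]$molecule$atoms$charge[1] <- -1L
  p0[[1]] <- ligand_pose(molecule(p0[[1]]$molecule$atoms,
                                  p0[[1]]$molecule$bonds,
                                  p0[[1]]$molecule$title,
                                  c(VENDOR = "synth")), 42.5)
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(p0, tf)
  p1 <- read_sdf(tf)
  expect_length(p1, length(p0))
  for (k in seq_along(p0)) {
    expect_equal(p1[[k]]$molecule$atoms$element, p0[[k]]$molecule$atoms$element)
    expect_equal(mol_coords(p1[[k]]$molecule),
                 round(mol_coords(p0[[k]]$molecule), 4),
                 ignore_attr = TRUE)
    expect_equal(p1[[k]]$molecule$bonds, p0[[k]]$molecule$bonds)
    expect_equal(p1[[k]]$molecule$atoms$charge, p0[[k]]$molecule$atoms$charge)
  }
  expect_equal(p1[[1]]$docking_score, 42.5)
  expect_equal(unname(p1[[1]]$molecule$properties["VENDOR"]), "synth")
  # write -> read -> write is byte-identical
  tf2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(p1, tf2)
  p2 <- read_sdf(tf2)
  write_sdf(p2, tf2)
  expect_identical(unname(tools::md5sum(tf)), unname(tools::md5sum(tf2)))
})

test_that("V3000 and inconsistent counts lines are rejected with index", {
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("m", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000",
               "M  END", "$$$$"), tf)
  expect_error(read_sdf(tf), "V3000")
  writeLines(c("m", "", "", "  5  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0", "M  END", "$$$$"), tf)
  expect_error(read_sdf(tf), "molecule 1")
})

test_that("write_table: header-only empty output, round trip, determinism", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_table(data.frame(a = numeric(), b = character()), tf)
  expect_equal(readLines(tf), "a\tb")
  df <- data.frame(a = c(1.234567891, 2), b = c("x", "y"))
  write_table(df, tf)
  back <- utils::read.delim(tf)
  expect_equal(back$a, signif(df$a, 6))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, tf2)
  expect_identical(unname(tools::md5sum(tf)), unname(tools::md5sum(tf2)))
})
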