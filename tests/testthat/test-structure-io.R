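test_that("PDB write/read round-trips and mmCIF gives identical coordinates", {
  ring <- ideal_ring("2H3")
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  cif_path <- withr::local_tempfile(fileext = ".cif")
  write_ring_pdb(ring, pdb_path)
  write_ring_cif(ring, cif_path)
  m_pdb <- read_structure(pdb_path)
  m_cif <- read_structure(cif_path)
  expect_equal(m_pdb$source$format, "pdb")
  expect_equal(m_cif$source$format, "mmcif")
  for (m in list(m_pdb, m_cif)) {
    got <- as.matrix(m$atoms[match(attr(ring, "labels"), m$atoms$name),
                             c("x", "y", "z")])
    expect_equal(got, unclass(ring), ignore_attr = TRUE, tolerance = 1e-3)
  }
  expect_equal(m_pdb$atoms[c("name", "x", "y", "z")],
               m_cif$atoms[c("name", "x", "y", "z")])
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")))
})

test_that("alternate locations resolve to the highest-occupancy record", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, altloc = "B"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 1, 1, 1, occ = 0.5, altloc = "A"),
    pdb_atom_line(4, "CA", "GLY", "A", 2, 8, 8, 8, occ = 0.5, altloc = "B"),
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 9) # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$resno == 2], 1) # tie -> altloc A
})

test_that("Kabsch superposition recovers rigid motions and rejects reflections", {
  path1 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_complex(path1)
  ref <- read_structure(path1)

  expect_equal(superpose_structures(ref, ref)$rmsd, 0, tolerance = 1e-12)

  set.seed(53)
  R <- random_rotation()
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_complex(path2)
  mob <- read_structure(path2)
  mob$atoms[c("x", "y", "z")] <- rigid_move(
    as.matrix(mob$atoms[c("x", "y", "z")]), R, c(3, -7, 11))
  fit <- superpose_structures(ref, mob)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$n, 3)

  # pre-rotating both inputs leaves the fitted RMSD unchanged
  mob2 <- mob
  mob2$atoms[c("x", "y", "z")] <- rigid_move(
    as.matrix(mob2$atoms[c("x", "y", "z")]))
  expect_equal(superpose_structures(ref, mob2)$rmsd, fit$rmsd,
               tolerance = 1e-9)

  expect_error(superpose_structures(ref, mob, selection = list(name = "NZ")),
               "fewer than 3")
  # mirrored coordinates demand an improper transform
  X <- matrix(stats::rnorm(15), 5, 3)
  Y <- X
  Y[, 3] <- -Y[, 3]
  expect_error(carbakin:::kabsch(X, Y), "reflection")
})

test_that("superposition matches the reference fitter on random point sets", {
  set.seed(59)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    X <- matrix(stats::rnorm(3 * n, sd = 3), n, 3)
    Y <- rigid_move(X) + matrix(stats::rnorm(3 * n, sd = 0.2), n, 3)
    ours <- carbakin:::kabsch(X, Y)
    fitted <- bio3d::fit.xyz(bio3d::as.xyz(as.vector(t(X))),
                             bio3d::as.xyz(as.vector(t(Y))),
                             1:(3 * n), 1:(3 * n))
    oracle_rmsd <- sqrt(mean(rowSums(
      (X - matrix(fitted, ncol = 3, byrow = TRUE))^2)))
    expect_equal(ours$rmsd, oracle_rmsd, tolerance = 1e-9)
  }
})

test_that("atom displacement reads frame-relative motion of a single atom", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_complex(path)
  ref <- read_structure(path)
  expect_equal(atom_displacement(ref, ref, list(name = "C1", resid = "LIG")), 0,
               ignore_attr = TRUE, tolerance = 1e-12)

  # shift the pseudo-anomeric carbon by exactly 1 A along x, protein fixed
  mob <- ref
  i <- with(mob$atoms, which(name == "C1" & resid == "LIG"))
  mob$atoms$x[i] <- mob$atoms$x[i] + 1
  d <- atom_displacement(ref, mob, list(name = "C1", resid = "LIG"))
  expect_equal(as.numeric(d), 1, tolerance = 1e-9)
  # symmetric under swapping reference and mobile
  expect_equal(as.numeric(atom_displacement(mob, ref,
                                            list(name = "C1", resid = "LIG"))),
               1, tolerance = 1e-9)
  # the protein frame itself is unmoved
  expect_lt(attr(d, "frame_rmsd"), 1e-12)
  expect_error(atom_displacement(ref, mob, list(name = "C9", resid = "LIG")),
               "not found")
})

test_that("ligand contacts find the constructed hydrogen bond and only it", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_complex(path)
  m <- read_structure(path)
  ct <- ligand_contacts(m, list(resid = "LIG"))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$ligand_atom, "O3")
  expect_equal(ct$residue, "ASP220")
  expect_equal(ct$distance, 2.8, tolerance = 1e-3)
  expect_true(all(ct$hbond))
  expect_equal(nrow(ligand_contacts(m, list(resid = "LIG"), cutoff = 0)), 0)
  expect_error(ligand_contacts(m, list(resid = "XXX")), "empty ligand")

  # stable under translation and ligand atom re-ordering
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_complex(path2, shift = c(12, -4, 7), perm = c(4, 2, 6, 1, 3, 5))
  ct2 <- ligand_contacts(read_structure(path2), list(resid = "LIG"))
  expect_equal(ct2$residue, ct$residue)
  expect_equal(ct2$distance, ct$distance, tolerance = 1e-3)

  sm <- contact_summary(ct)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$distance, 2.8, tolerance = 1e-3)
})
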