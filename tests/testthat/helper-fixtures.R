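# Shared fixture builders: random rate schemes, rigid motions, and small
# synthetic PDB/mmCIF structures written at test time.

random_scheme <- function() {
  rate_scheme(
    k1 = 10^stats::runif(1, 3, 7),
    k_minus1 = 10^stats::runif(1, -1, 3),
    k3 = 10^stats::runif(1, -4, 1),
    k5 = 10^stats::runif(1, -5, 0)
  )
}

# independent multiplicative-noise application (deliberately not the
# package's own noise path)
apply_noise_seeded <- function(mu, cv, seed) {
  set.seed(seed)
  mu * (1 + cv * stats::rnorm(length(mu)))
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_move <- function(xyz, R = random_rotation(), t = stats::rnorm(3, sd = 5)) {
  sweep(as.matrix(xyz) %*% R, 2, t, "+")
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, type = "ATOM", altloc = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, altloc, resid, chain, resno, x, y, z, occ, b,
          substr(name, 1, 1))
}

# Minimal synthetic protein-plus-ligand complex: three residues with CA
# (plus one polar side-chain O), one water, and a six-atom carbasugar ring
# whose C3 hydroxyl O3 sits 2.8 A from the Asp OD1.
write_synthetic_complex <- function(path, shift = c(0, 0, 0), perm = NULL) {
  ring <- unclass(carbakin::ideal_ring("2H3",
    labels = c("C6", "C1", "C2", "C3", "C4", "C5")))
  lab <- c("C6", "C1", "C2", "C3", "C4", "C5")
  lines <- character(0)
  s <- 0
  add <- function(name, resid, chain, resno, p, type = "ATOM") {
    s <<- s + 1
    lines <<- c(lines, pdb_atom_line(s, name, resid, chain, resno,
                                     p[1] + shift[1], p[2] + shift[2],
                                     p[3] + shift[3], type = type))
  }
  add("CA", "ASP", "A", 220, c(8, 0, 0))
  # OD1 sits 2.8 A beyond the ligand O3 along +x: exactly one H-bond pair
  add("OD1", "ASP", "A", 220, ring[4, ] + c(4.2, 0, 0))
  add("CA", "LYS", "A", 325, c(0, 8, 0))
  add("NZ", "LYS", "A", 325, c(0, 6, 0))
  add("CA", "TYR", "A", 191, c(0, 0, 8))
  add("O", "HOH", "A", 501, c(-5, -5, 0), type = "HETATM")
  ord <- if (is.null(perm)) 1:6 else perm
  for (i in ord) add(lab[i], "LIG", "A", 400, ring[i, ], type = "HETATM")
  # one ligand hydroxyl oxygen 2.8 A from ASP OD1
  add("O3", "LIG", "A", 400, ring[4, ] + c(1.4, 0, 0), type = "HETATM")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# mmCIF rendering of a six-atom ring identical to write_ring_pdb() output
write_ring_cif <- function(ring, path, resname = "RNG") {
  xyz <- unclass(ring)
  lab <- attr(ring, "labels")
  hdr <- c(
    "data_ring", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- vapply(1:6, function(i) {
    sprintf("HETATM %d %s %s . %s A 1 1 ? %.3f %.3f %.3f 1.00 0.00 1 %s A %s 1",
            i, substr(lab[i], 1, 1), lab[i], resname,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], resname, lab[i])
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
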