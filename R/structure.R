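#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Thin normalizing wrapper over [bio3d::read.pdb()] / [bio3d::read.cif()].
#' All ATOM/HETATM records are kept; alternate locations are resolved by
#' keeping the highest-occupancy record (ties broken in favor of altloc
#' `'A'`/first).
#'
#' @param path file path.
#' @param format `"pdb"` or `"mmcif"`; guessed from the file extension by
#'   default.
#' @return object of class `structure_model`: list with `atoms` (data.frame:
#'   `element`, `name`, `resid`, `resno`, `chain`, `x`, `y`, `z`, `occupancy`,
#'   `b`, `type`) and `source` (path + format).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
      else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    ),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  a <- parsed$atom
  atoms <- data.frame(
    element = if (!is.null(a$elesy)) a$elesy else substr(trimws(a$elety), 1, 1),
    name = trimws(a$elety),
    resid = a$resid,
    resno = a$resno,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt) | a$alt == "", NA_character_, a$alt),
    type = a$type,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in ", path)
  # resolve altlocs: highest occupancy, tie -> alphabetically first ('A')
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$alt, na.last = FALSE)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resid,
                                   atoms$name, sep = "|")), ]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$name), ]
  rownames(atoms) <- NULL
  atoms$alt <- NULL
  structure(list(atoms = atoms, source = list(path = path, format = format)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chains (%s, %s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              x$source$format, basename(x$source$path)))
  invisible(x)
}

# matched coordinate matrix for a selection
select_xyz <- function(model, selection) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  for (f in intersect(names(selection), c("name", "resid", "resno", "chain",
                                          "element", "type")))
    keep <- keep & a[[f]] %in% selection[[f]]
  a[keep, , drop = FALSE]
}

#' Rigid-body superposition (Kabsch)
#'
#' Least-squares proper-rotation fit of matched atom pairs via the singular
#' value decomposition of the covariance matrix (orthogonal Procrustes).
#' Atom pairs are matched by `(chain, resno, name)` within the selection.
#' An error is raised when fewer than 3 pairs match or when the optimal
#' orthogonal transform would be a reflection.
#'
#' @param ref,mobile `structure_model` objects.
#' @param selection named list of atom filters applied to both models, e.g.
#'   `list(name = "CA")` (default: all alpha-carbons) or
#'   `list(name = "CA", chain = "A")`.
#' @return list with `R` (3 x 3 rotation applied to mobile), `t`
#'   (translation), `rmsd` (Angstrom over the selection), `n` (pairs used)
#'   and `transform(xyz)` applying the fit to an n x 3 matrix.
#' @export
superpose_structures <- function(ref, mobile, selection = list(name = "CA")) {
  ra <- select_xyz(ref, selection)
  ma <- select_xyz(mobile, selection)
  key_r <- paste(ra$chain, ra$resno, ra$name, sep = "|")
  key_m <- paste(ma$chain, ma$resno, ma$name, sep = "|")
  common <- intersect(key_r, key_m)
  if (length(common) < 3) stop("fewer than 3 matched atom pairs")
  X <- as.matrix(ra[match(common, key_r), c("x", "y", "z")]) # ref
  Y <- as.matrix(ma[match(common, key_m), c("x", "y", "z")]) # mobile
  fit <- kabsch(X, Y)
  fit$n <- length(common)
  fit
}

# Kabsch fit of mobile Y onto reference X (both n x 3)
kabsch <- function(X, Y) {
  if (nrow(X) < 3) stop("fewer than 3 matched atom pairs")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(t(Yc) %*% Xc)
  if (det(s$u %*% t(s$v)) < 0) {
    # a planar/degenerate point set leaves the out-of-plane axis free: a
    # proper rotation is still optimal; otherwise a true reflection is needed
    if (s$d[3] > 1e-8 * s$d[1])
      stop("optimal superposition requires a reflection; proper rotations only")
    s$u[, 3] <- -s$u[, 3]
  }
  R <- s$u %*% t(s$v)  # row-vector convention: y_fit = (y - cy) %*% R + cx
  Yfit <- Yc %*% R
  rmsd <- sqrt(mean(rowSums((Yfit - Xc)^2)))
  transform <- function(xyz) sweep(sweep(as.matrix(xyz), 2, cy) %*% R, 2, cx, "+")
  list(R = R, t = cx - as.vector(cy %*% R), rmsd = rmsd, transform = transform)
}

#' Displacement of one atom between two superposed structures
#'
#' Superposes `mobile` onto `ref` over `superpose_selection` (default all
#' alpha-carbons, i.e. the protein frame), then reports the Euclidean
#' distance between the named atom's position in the two models. This is the
#' measure behind statements like "formation of the covalent bond displaces
#' the pseudo-anomeric carbon C1 by ~2 Angstrom".
#'
#' @param ref,mobile `structure_model` objects.
#' @param atom named list identifying one atom in both models, e.g.
#'   `list(name = "C1", resid = "LIG")`.
#' @param superpose_selection selection for the frame fit (see
#'   [superpose_structures()]).
#' @return distance in Angstrom, with the superposition RMSD as attribute
#'   `"frame_rmsd"`.
#' @export
atom_displacement <- function(ref, mobile, atom,
                              superpose_selection = list(name = "CA")) {
  fit <- superpose_structures(ref, mobile, superpose_selection)
  pr <- select_xyz(ref, atom)
  pm <- select_xyz(mobile, atom)
  if (nrow(pr) == 0 || nrow(pm) == 0)
    stop("atom not found in both models: ",
         paste(names(atom), unlist(atom), sep = "=", collapse = ", "))
  if (nrow(pr) > 1 || nrow(pm) > 1)
    stop("atom selector matches more than one atom")
  moved <- fit$transform(as.matrix(pm[, c("x", "y", "z")]))
  d <- sqrt(sum((moved - as.matrix(pr[, c("x", "y", "z")]))^2))
  attr(d, "frame_rmsd") <- fit$rmsd
  d
}

#' Polar contacts between a ligand and its protein environment
#'
#' Finds all protein nitrogen/oxygen atoms (and water oxygens) within
#' `cutoff` of the ligand's N/O/F atoms. With the default 3.5 Angstrom
#' heavy-atom donor-acceptor cutoff these are reported as hydrogen bonds (no
#' angular term: deposited structures carry no hydrogens).
#'
#' @param model a `structure_model`.
#' @param ligand named list selecting the ligand atoms, e.g.
#'   `list(resid = "LIG")`; must select at least one atom.
#' @param cutoff donor-acceptor distance cutoff (Angstrom, default 3.5).
#' @param water_resids residue names treated as water (`HOH`, `WAT`).
#' @return data.frame of class `contact_records`, sorted by distance:
#'   `ligand_atom`, `residue` (name + number), `resid`, `resno`, `chain`,
#'   `protein_atom`, `distance`, `hbond` (logical, distance <= cutoff — all
#'   TRUE by construction, kept for clarity when cutoffs are widened).
#' @export
ligand_contacts <- function(model, ligand, cutoff = 3.5,
                            water_resids = c("HOH", "WAT")) {
  la <- select_xyz(model, ligand)
  if (nrow(la) == 0) stop("empty ligand selection")
  la <- la[la$element %in% c("N", "O", "F"), , drop = FALSE]
  env <- model$atoms
  lig_key <- paste(la$chain, la$resno, la$resid, sep = "|")
  env <- env[!(paste(env$chain, env$resno, env$resid, sep = "|") %in% lig_key), ]
  env <- env[env$element %in% c("N", "O") &
               (env$type == "ATOM" | env$resid %in% water_resids), , drop = FALSE]
  if (nrow(env) == 0 || cutoff <= 0) {
    out <- data.frame(ligand_atom = character(0), residue = character(0),
                      resid = character(0), resno = integer(0),
                      chain = character(0), protein_atom = character(0),
                      distance = numeric(0), hbond = logical(0))
    class(out) <- c("contact_records", "data.frame")
    return(out)
  }
  lx <- as.matrix(la[, c("x", "y", "z")])
  ex <- as.matrix(env[, c("x", "y", "z")])
  d2 <- outer(rowSums(lx^2), rep(1, nrow(ex))) +
    outer(rep(1, nrow(lx)), rowSums(ex^2)) - 2 * lx %*% t(ex)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  out <- data.frame(
    ligand_atom = la$name[hit[, 1]],
    residue = paste0(env$resid[hit[, 2]], env$resno[hit[, 2]]),
    resid = env$resid[hit[, 2]],
    resno = env$resno[hit[, 2]],
    chain = env$chain[hit[, 2]],
    protein_atom = env$name[hit[, 2]],
    distance = sqrt(pmax(d2[hit], 0)),
    stringsAsFactors = FALSE
  )
  out$hbond <- out$distance <= cutoff
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Per-residue summary of ligand contacts
#'
#' @param contacts a `contact_records` table from [ligand_contacts()].
#' @return data.frame with one row per (ligand atom, residue) pair and the
#'   shortest distance.
#' @export
contact_summary <- function(contacts) {
  if (nrow(contacts) == 0) return(contacts)
  agg <- stats::aggregate(distance ~ ligand_atom + residue, data = contacts, FUN = min)
  agg[order(agg$ligand_atom, agg$distance), ]
}
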