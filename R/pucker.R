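#' Ordered six-membered ring coordinates
#'
#' Container for an ordered six-atom ring. The ordering convention determines
#' the meaning of the puckering angles: for pyranoses use
#' `O5, C1, C2, C3, C4, C5` (ring oxygen first), under which an ideal
#' \eqn{^4C_1} chair sits at theta = 0. For carbasugars, [map_carbasugar_ring()]
#' places the pseudo-ring-oxygen carbon in the O5 slot so conformer names
#' match pyranose nomenclature.
#'
#' @param xyz 6 x 3 numeric matrix of Cartesian coordinates (Angstrom), rows
#'   in ring order.
#' @param labels six atom labels.
#' @return object of class `ring_coordinates`.
#' @export
ring_coordinates <- function(xyz, labels = c("O5", "C1", "C2", "C3", "C4", "C5")) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || nrow(xyz) != 6 || ncol(xyz) != 3)
    stop("ring must be a 6 x 3 coordinate matrix")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (length(labels) != 6) stop("need 6 atom labels")
  d <- sqrt(rowSums((xyz - xyz[c(2:6, 1), ])^2))
  if (any(d < 1.2 | d > 1.8))
    warning("consecutive ring distances outside [1.2, 1.8] Angstrom")
  structure(xyz, labels = labels, class = c("ring_coordinates", "matrix", "array"))
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Centers the ring at its centroid, defines the mean plane from the two
#' first-harmonic position sums
#' \eqn{R' = \sum_j r_j \sin(2\pi (j-1)/6)},
#' \eqn{R'' = \sum_j r_j \cos(2\pi (j-1)/6)} (unit normal
#' \eqn{n = R' \times R'' / |R' \times R''|}), takes signed out-of-plane
#' displacements \eqn{z_j = r_j \cdot n}, and computes
#' \deqn{q_2 \cos\phi_2 = \sqrt{1/3} \sum_j z_j \cos(4\pi (j-1)/6), \quad
#'       q_2 \sin\phi_2 = -\sqrt{1/3} \sum_j z_j \sin(4\pi (j-1)/6),}
#' \deqn{q_3 = \sqrt{1/6} \sum_j (-1)^{j-1} z_j, \quad
#'       Q = \sqrt{q_2^2 + q_3^2}, \quad \theta = \mathrm{atan2}(q_2, q_3).}
#' The result is invariant under rigid rotation and translation. Under the
#' `O5, C1..C5` ordering theta = 0 is the \eqn{^4C_1} chair and theta = 180
#' the \eqn{^1C_4} chair; boats and twist-boats lie on the theta = 90 equator.
#'
#' @param ring a [ring_coordinates()] (or 6 x 3 matrix).
#' @return object of class `pucker_cp`: list with `Q` (Angstrom), `theta`,
#'   `phi` (degrees), components `q2`, `phi2`, `q3`, and logical `planar`
#'   (TRUE when `Q < 1e-4` Angstrom, where theta and phi are undefined and
#'   returned as `NA`).
#' @references Cremer & Pople (1975) J Am Chem Soc 97:1354. General
#'   definition of ring puckering coordinates.
#' @export
#' @examples
#' cremer_pople(ideal_ring(Q = 0.45, theta = 50.8, phi = 330))
cremer_pople <- function(ring) {
  if (!inherits(ring, "ring_coordinates")) ring <- ring_coordinates(ring)
  r <- sweep(unclass(ring), 2, colMeans(unclass(ring)))
  j <- 0:5
  Rp <- colSums(r * sin(2 * pi * j / 6))
  Rpp <- colSums(r * cos(2 * pi * j / 6))
  n <- c(Rp[2] * Rpp[3] - Rp[3] * Rpp[2],
         Rp[3] * Rpp[1] - Rp[1] * Rpp[3],
         Rp[1] * Rpp[2] - Rp[2] * Rpp[1])
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("degenerate ring geometry: cannot define mean plane")
  n <- n / nn
  z <- as.vector(r %*% n)

  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / 6) * sum((-1)^j * z)
  Q <- sqrt(q2^2 + q3^2)
  planar <- Q < 1e-4
  phi2 <- if (planar || q2 == 0) NA_real_ else {
    p <- (atan2(q2s, q2c) * 180 / pi) %% 360
    if (p > 360 - 1e-9) 0 else p
  }
  theta <- if (planar) NA_real_ else atan2(q2, q3) * 180 / pi
  structure(list(Q = Q, theta = theta, phi = phi2,
                 q2 = q2, phi2 = phi2, q3 = q3, planar = planar),
            class = "pucker_cp")
}

#' @export
print.pucker_cp <- function(x, ...) {
  if (x$planar) {
    cat(sprintf("Cremer-Pople: planar (Q = %.5f A)\n", x$Q))
  } else {
    cat(sprintf("Cremer-Pople: Q = %.4f A, theta = %.2f deg, phi = %.2f deg\n",
                x$Q, x$theta, if (is.na(x$phi)) 0 else x$phi))
  }
  invisible(x)
}

#' Hill-Reilly flap angles of a six-membered ring
#'
#' Triangular decomposition: the reference plane passes through the
#' alternating atoms 1, 3, 5 (of the ring ordering); the three flaps are the
#' triangles (1, 2, 3), (3, 4, 5) and (5, 6, 1), hinged on the 1-3, 3-5 and
#' 5-1 edges. Each puckering angle is the signed dihedral between the flap
#' plane and the reference plane about its hinge; the sign is positive when
#' the flap atom (2, 4 or 6) lies on the side of the reference plane pointed
#' to by its right-handed normal (atoms 1 -> 3 -> 5). A planar ring gives
#' (0, 0, 0); mirroring the ring through its plane flips all signs.
#'
#' @param ring a [ring_coordinates()].
#' @return object of class `pucker_hr`: numeric vector of the three flap
#'   angles (degrees), named by the flap atom label.
#' @references Hill & Reilly (2007) J Chem Inf Model 47:1031. Puckering
#'   coordinates from a triangular decomposition.
#' @export
hill_reilly <- function(ring) {
  if (!inherits(ring, "ring_coordinates")) ring <- ring_coordinates(ring)
  r <- unclass(ring)
  labels <- attr(ring, "labels")
  p1 <- r[1, ]; p3 <- r[3, ]; p5 <- r[5, ]
  n0 <- crossp(p3 - p1, p5 - p1)
  if (sqrt(sum(n0^2)) < 1e-9) stop("degenerate central plane (atoms 1, 3, 5)")
  n0 <- n0 / sqrt(sum(n0^2))
  flap <- function(a, f, b) {
    # hinge a -> b; flap plane through (a, f, b)
    h <- (b - a) / sqrt(sum((b - a)^2))
    n1 <- crossp(f - a, b - a)
    n1 <- n1 / sqrt(sum(n1^2))
    -atan2(sum(crossp(n0, n1) * h), sum(n0 * n1)) * 180 / pi
  }
  ang <- c(flap(p1, r[2, ], p3), flap(p3, r[4, ], p5), flap(p5, r[6, ], p1))
  names(ang) <- labels[c(2, 4, 6)]
  structure(ang, class = "pucker_hr")
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Canonical conformer table (38 entries)
#'
#' Builds the (theta, phi) positions of all 38 canonical six-ring conformers
#' constructively, rather than from a transcribed literature table: for each
#' name, the defining atoms are displaced by +/- `delta` from the plane of
#' the remaining atoms on an ideal hexagon and the Cremer-Pople coordinates
#' of that geometry are computed.
#'
#' * 2 chairs (`4C1`, `1C4`): alternating +/- displacements (theta 0 / 180).
#' * 12 envelopes (`2E` = C2 above; `E2` = C2 below; etc.): one atom
#'   displaced.
#' * 12 half-chairs (`2H3` = C2 above, C3 below; etc.): two adjacent atoms
#'   displaced oppositely.
#' * 6 boats (`1,4B` = C1 and C4 above; `B1,4` = below): two para atoms
#'   displaced together (theta = 90).
#' * 6 twist-boats/skews (`1S3` = C1 above, C3 below; etc.): two meta atoms
#'   displaced oppositely (theta = 90). Each equator point admits two such
#'   constructions; the conventional name (`1S3`, `1S5`, `2SO`, `3S1`,
#'   `5S1`, `OS2`) is kept.
#'
#' Names use plain text with the ring-oxygen slot written `O`: superscripts
#' precede the letter, subscripts follow (so IUPAC ^2H_3 is `"2H3"` and
#' B_{2,5} is `"B2,5"`). The latitude separating half-chairs from envelopes
#' is whatever the construction yields; name assignment is independent of
#' `delta`.
#'
#' @param delta out-of-plane displacement used in the construction
#'   (Angstrom, default 0.25).
#' @param radius hexagon radius (Angstrom, default 1.46).
#' @return data.frame with columns `name`, `type` (`C`, `E`, `H`, `B`, `S`),
#'   `theta`, `phi` (degrees).
#' @export
#' @examples
#' tab <- canonical_conformers()
#' subset(tab, name %in% c("4C1", "2H3", "2E", "1S3"))
canonical_conformers <- function(delta = 0.25, radius = 1.46) {
  atom <- c("O", "1", "2", "3", "4", "5") # slot -> nomenclature label
  build <- function(z) {
    ang <- -2 * pi * (0:5) / 6 # same handedness as ideal_ring()
    ring_coordinates(cbind(radius * cos(ang), radius * sin(ang), z))
  }
  cp_of <- function(z) {
    p <- suppressWarnings(cremer_pople(build(z)))
    c(theta = p$theta, phi = if (is.na(p$phi)) 0 else p$phi)
  }
  rows <- list()
  add <- function(name, type, z) {
    tp <- cp_of(z)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, type = type, theta = unname(tp["theta"]),
      phi = unname(tp["phi"]), stringsAsFactors = FALSE)
  }

  # chairs: alternating displacement; O5/C2/C4 up <=> C4 above, C1 below -> 4C1
  add("4C1", "C", delta * (-1)^(0:5))
  add("1C4", "C", -delta * (-1)^(0:5))

  # envelopes: single atom out of plane
  for (s in 1:6) {
    z <- numeric(6); z[s] <- delta
    add(paste0(atom[s], "E"), "E", z)
    add(paste0("E", atom[s]), "E", -z)
  }

  # half-chairs: adjacent pair, opposite displacement
  for (s in 1:6) {
    s2 <- s %% 6 + 1
    z <- numeric(6); z[s] <- delta; z[s2] <- -delta
    add(paste0(atom[s], "H", atom[s2]), "H", z)
    add(paste0(atom[s2], "H", atom[s]), "H", -z)
  }

  # boats: para pair displaced together
  for (s in 1:3) {
    s2 <- s + 3
    z <- numeric(6); z[c(s, s2)] <- delta
    pair <- paste0(atom[s], ",", atom[s2])
    add(paste0(pair, "B"), "B", z)
    add(paste0("B", pair), "B", -z)
  }

  # twist-boats: meta pair, opposite displacement; keep conventional names
  skew_names <- c("1S3", "1S5", "2SO", "3S1", "5S1", "OS2")
  for (s in 1:6) {
    for (step in c(2, -2)) {
      s2 <- (s - 1 + step) %% 6 + 1
      nm <- paste0(atom[s], "S", atom[s2])
      if (!nm %in% skew_names) next
      z <- numeric(6); z[s] <- delta; z[s2] <- -delta
      add(nm, "S", z)
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# great-circle distance (degrees) between two (theta, phi) points
arc_distance <- function(theta1, phi1, theta2, phi2) {
  t1 <- theta1 * pi / 180; t2 <- theta2 * pi / 180
  dp <- (phi1 - phi2) * pi / 180
  cx <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dp)
  acos(pmin(1, pmax(-1, cx))) * 180 / pi
}

#' Classify a pucker against the canonical conformers
#'
#' Nearest canonical conformer by great-circle (arc) distance on the
#' Cremer-Pople sphere `(theta, phi)`; the puckering amplitude Q does not
#' enter the classification. When the second-nearest conformer is closer
#' than `blend_margin` degrees beyond the nearest, the assignment is reported
#' as a blend (e.g. `"2H3/2E"`), mirroring the common description of rings
#' lying between two canonical forms.
#'
#' @param pucker a `pucker_cp` (from [cremer_pople()]) or a
#'   [ring_coordinates()] object.
#' @param table canonical table from [canonical_conformers()].
#' @param blend_margin blend threshold in degrees (default 5).
#' @return object of class `conformer_assignment`: list with `name`,
#'   `distance` (deg), `second_name`, `second_distance`, `blend` (string or
#'   `NA`), `planar`.
#' @export
#' @examples
#' classify_conformer(ideal_ring("2H3"))
classify_conformer <- function(pucker, table = canonical_conformers(),
                               blend_margin = 5) {
  if (inherits(pucker, "ring_coordinates")) pucker <- cremer_pople(pucker)
  stopifnot(inherits(pucker, "pucker_cp"))
  if (pucker$planar) {
    return(structure(list(name = "planar", distance = NA_real_,
                          second_name = NA_character_,
                          second_distance = NA_real_, blend = NA_character_,
                          planar = TRUE),
                     class = "conformer_assignment"))
  }
  phi <- if (is.na(pucker$phi)) 0 else pucker$phi
  d <- arc_distance(pucker$theta, phi, table$theta, table$phi)
  o <- order(d)
  blend <- if (d[o[2]] - d[o[1]] < blend_margin)
    paste0(table$name[o[1]], "/", table$name[o[2]]) else NA_character_
  structure(list(name = table$name[o[1]], distance = d[o[1]],
                 second_name = table$name[o[2]], second_distance = d[o[2]],
                 blend = blend, planar = FALSE),
            class = "conformer_assignment")
}

#' @export
print.conformer_assignment <- function(x, ...) {
  if (x$planar) {
    cat("Conformer: planar ring\n")
    return(invisible(x))
  }
  cat(sprintf("Conformer: %s (arc distance %.2f deg; next %s at %.2f deg)\n",
              x$name, x$distance, x$second_name, x$second_distance))
  if (!is.na(x$blend)) cat("  blend:", x$blend, "\n")
  invisible(x)
}

#' Order a sugar or carbasugar ring for pyranose nomenclature
#'
#' Extracts the six ring atoms from a set of named atom coordinates and
#' orders them so conformer names carry pyranose meaning. For a pyranose the
#' order is `O5, C1, C2, C3, C4, C5`. For a cyclohexene carbasugar, C6 (the
#' carbon occupying the position of the endocyclic ring oxygen) takes the O5
#' slot: `C6, C1, C2, C3, C4, C5`.
#'
#' @param atoms data.frame with columns `name`, `x`, `y`, `z` (e.g. the
#'   `atoms` table of [read_structure()], possibly subset to one residue).
#' @param ring_atoms six atom names in ring order, first the ring-oxygen
#'   (-equivalent) atom. Defaults to the pyranose names; use
#'   `c("C6", "C1", ..., "C5")` for a carbasugar, or set
#'   `carbasugar = TRUE`.
#' @param carbasugar convenience switch selecting the carbasugar ordering.
#' @return a [ring_coordinates()] with pyranose-equivalent ordering.
#' @export
map_carbasugar_ring <- function(atoms,
                                ring_atoms = if (carbasugar)
                                  c("C6", "C1", "C2", "C3", "C4", "C5")
                                else c("O5", "C1", "C2", "C3", "C4", "C5"),
                                carbasugar = FALSE) {
  stopifnot(all(c("name", "x", "y", "z") %in% names(atoms)))
  idx <- match(ring_atoms, atoms$name)
  if (anyNA(idx))
    stop("missing ring atom(s): ", paste(ring_atoms[is.na(idx)], collapse = ", "))
  ring_coordinates(as.matrix(atoms[idx, c("x", "y", "z")]), labels = ring_atoms)
}
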