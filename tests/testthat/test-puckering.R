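test_that("Cremer-Pople round-trips ideal rings over a (Q, theta, phi) grid", {
  for (Q in c(0.25, 0.45, 0.6)) {
    for (theta in c(5, 50.8, 90, 135, 175)) {
      for (phi in c(0, 30, 123.4, 210, 330)) {
        p <- cremer_pople(ideal_ring(Q = Q, theta = theta, phi = phi))
        expect_equal(p$Q, Q, tolerance = 1e-6)
        expect_equal(p$theta, theta, tolerance = 1e-6)
        expect_equal(p$phi, phi, tolerance = 1e-6)
        expect_equal(p$Q^2, p$q2^2 + p$q3^2, tolerance = 1e-9)
        expect_equal(cos(p$theta * pi / 180), p$q3 / p$Q, tolerance = 1e-9)
      }
    }
  }
})

test_that("planar rings are flagged and poles have no azimuth ambiguity", {
  p <- cremer_pople(ideal_ring(Q = 0))
  expect_true(p$planar)
  expect_true(is.na(p$theta))
  chair <- cremer_pople(ideal_ring(Q = 0.5, theta = 0))
  expect_equal(chair$theta, 0, tolerance = 1e-9)
  expect_equal(chair$q3, 0.5, tolerance = 1e-12)
  inv <- cremer_pople(ideal_ring(Q = 0.5, theta = 180))
  expect_equal(inv$theta, 180, tolerance = 1e-9)
})

test_that("puckering descriptors are invariant under rigid motion", {
  set.seed(31)
  ring <- ideal_ring(Q = 0.52, theta = 67, phi = 141)
  p0 <- cremer_pople(ring)
  h0 <- hill_reilly(ring)
  for (i in 1:20) {
    moved <- ring_coordinates(rigid_move(unclass(ring)))
    p <- cremer_pople(moved)
    expect_equal(p$Q, p0$Q, tolerance = 1e-9)
    expect_equal(p$theta, p0$theta, tolerance = 1e-9)
    expect_equal(p$phi, p0$phi, tolerance = 1e-9)
    expect_equal(as.numeric(hill_reilly(moved)), as.numeric(h0),
                 tolerance = 1e-9)
  }
})

test_that("Hill-Reilly flap angles behave per definition", {
  expect_equal(as.numeric(hill_reilly(ideal_ring(Q = 0))), c(0, 0, 0))
  ch <- as.numeric(hill_reilly(ideal_ring(Q = 0.5, theta = 0)))
  expect_equal(abs(ch), rep(abs(ch[1]), 3), tolerance = 1e-9) # 3-fold symmetry
  # mirroring through the mean plane flips every sign
  r <- unclass(ideal_ring(Q = 0.5, theta = 0))
  r[, 3] <- -r[, 3]
  expect_equal(as.numeric(hill_reilly(ring_coordinates(r))), -ch,
               tolerance = 1e-9)
})

test_that("Hill-Reilly and Cremer-Pople agree on planarity and chair/boat", {
  tab <- canonical_conformers()
  for (i in seq_len(nrow(tab))) {
    ring <- ideal_ring(tab$name[i])
    hr <- as.numeric(hill_reilly(ring))
    cp <- cremer_pople(ring)
    expect_false(cp$planar)
    expect_gt(max(abs(hr)), 1) # visibly puckered by both descriptors
    if (tab$type[i] == "C") {
      # chair: all three flap atoms on the same side
      expect_equal(length(unique(sign(hr))), 1L)
      expect_gt(abs(cp$q3), abs(cp$q2))
    }
    if (tab$type[i] %in% c("B", "S")) {
      # equator forms: flaps split across the reference plane, q3 ~ 0
      expect_gt(length(unique(sign(hr))), 1L)
      expect_lt(abs(cp$q3), 1e-6)
    }
  }
})

test_that("the canonical table has 38 distinct, delta-independent entries", {
  tab <- canonical_conformers()
  expect_equal(nrow(tab), 38)
  expect_equal(length(unique(tab$name)), 38)
  expect_equal(as.vector(table(tab$type)[c("C", "B", "S", "H", "E")]),
               c(2, 6, 6, 12, 12))
  # no two canonical points within 1 degree of arc
  for (i in 1:37) {
    d <- carbakin:::arc_distance(tab$theta[i], tab$phi[i],
                                 tab$theta[-(1:i)], tab$phi[-(1:i)])
    expect_gt(min(d), 1)
  }
  expect_equal(tab$theta[tab$name == "4C1"], 0, tolerance = 1e-9)
  expect_equal(tab$theta[tab$name == "1C4"], 180, tolerance = 1e-9)
  # name assignment does not depend on the construction displacement
  tab_small <- canonical_conformers(delta = 0.1)
  tab_large <- canonical_conformers(delta = 0.4)
  expect_identical(tab_small$name, tab$name)
  expect_identical(tab_large$name, tab$name)
  for (nm in c("2H3", "2E", "1S3", "B2,5")) {
    expect_equal(classify_conformer(ideal_ring(nm), tab_small)$name, nm)
    expect_equal(classify_conformer(ideal_ring(nm), tab_large)$name, nm)
  }
})

test_that("classification finds the nearest conformer and reports blends", {
  tab <- canonical_conformers()
  for (i in seq_len(nrow(tab))) {
    a <- classify_conformer(ideal_ring(tab$name[i]), tab)
    expect_equal(a$name, tab$name[i])
    expect_lt(a$distance, 1e-6)
    expect_false(a$name == a$second_name)
  }
  # midpoint of the 2H3 -- 2E arc is reported as their blend
  t1 <- tab[tab$name == "2H3", ]
  t2 <- tab[tab$name == "2E", ]
  mid <- ideal_ring(Q = 0.5, theta = (t1$theta + t2$theta) / 2,
                    phi = (t1$phi + t2$phi) / 2)
  a <- classify_conformer(mid, tab)
  expect_true(a$name %in% c("2H3", "2E"))
  expect_false(is.na(a$blend))
  expect_setequal(strsplit(a$blend, "/")[[1]], c("2H3", "2E"))
  # planar input
  expect_equal(classify_conformer(ideal_ring(Q = 0), tab)$name, "planar")
})

test_that("classification agrees with a brute-force nearest-point search", {
  tab <- canonical_conformers()
  # independent arc distance via 3-vector dot products
  to_xyz <- function(theta, phi) {
    t <- theta * pi / 180; p <- phi * pi / 180
    c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  }
  ref <- t(mapply(to_xyz, tab$theta, tab$phi))
  set.seed(47)
  u <- matrix(stats::rnorm(3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  for (i in 1:1000) {
    theta <- acos(u[i, 3]) * 180 / pi
    phi <- (atan2(u[i, 2], u[i, 1]) * 180 / pi) %% 360
    brute <- tab$name[which.max(ref %*% u[i, ])]
    got <- classify_conformer(cremer_pople(ideal_ring(Q = 0.5, theta = theta,
                                                      phi = phi)), tab)
    expect_equal(got$name, brute)
  }
})

test_that("ring extraction orders sugar and carbasugar atoms for nomenclature", {
  ring <- ideal_ring("2H3")
  xyz <- unclass(ring)
  # pyranose: O5 first
  atoms <- data.frame(name = c("O5", "C1", "C2", "C3", "C4", "C5"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  shuffled <- atoms[c(3, 1, 6, 2, 5, 4), ]
  rc <- map_carbasugar_ring(shuffled)
  expect_equal(attr(rc, "labels")[1], "O5")
  expect_equal(classify_conformer(rc)$name, "2H3")
  # carbasugar: C6 takes the ring-oxygen slot
  atoms$name <- c("C6", "C1", "C2", "C3", "C4", "C5")
  rc6 <- map_carbasugar_ring(atoms, carbasugar = TRUE)
  expect_equal(attr(rc6, "labels")[1], "C6")
  expect_equal(classify_conformer(rc6)$name, "2H3")
  expect_error(map_carbasugar_ring(atoms[-2, ], carbasugar = TRUE), "C1")
  # reversing the traversal flips ring chirality: the chair maps to its
  # antipode, which is why the ordering convention is part of the contract
  chair <- unclass(ideal_ring(Q = 0.5, theta = 0))
  rev_ring <- ring_coordinates(chair[c(1, 6:2), ])
  expect_equal(classify_conformer(rev_ring)$name, "1C4")
})
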