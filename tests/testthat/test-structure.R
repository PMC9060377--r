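axis_z <- list(point = c(0, 0, 0), dir = c(0, 0, 1))

test_that("pore-axis distance is perpendicular Euclidean distance", {
  s <- structure_model(data.frame(position = 1:3, aa = c("A", "L", "G"),
                                  x = c(0, 3, -3), y = c(0, 4, -4),
                                  z = c(12, 7, -2)),
                       pore_axis = axis_z)
  expect_equal(pore_axis_distance(s, 1), 0)
  expect_equal(pore_axis_distance(s, 2), 5)
  expect_equal(pore_axis_distance(s, 3), 5)  # rotation about the axis
  expect_error(pore_axis_distance(s, 99), "not resolved")
})

test_that("geometric features are invariant to in-plane rigid motion", {
  s <- small_structure()
  th <- 0.73; dx <- 5.2; dy <- -3.1
  rot <- structure_model(data.frame(
    position = s$position, aa = s$aa,
    x = cos(th) * s$x - sin(th) * s$y + dx,
    y = sin(th) * s$x + cos(th) * s$y + dy,
    z = s$z))
  for (p in c(1, 17, 44)) {
    expect_equal(pore_axis_distance(rot, p), pore_axis_distance(s, p),
                 tolerance = 1e-9)
    expect_equal(functional_density(rot, p, "polarizability", 6.5),
                 functional_density(s, p, "polarizability", 6.5),
                 tolerance = 1e-9)
    expect_equal(neighbor_vector(rot, p), neighbor_vector(s, p),
                 tolerance = 1e-9)
    expect_equal(membrane_burial(rot, p), membrane_burial(s, p))
  }
})

test_that("membrane burial is a symmetric plateau with smooth decay", {
  expect_equal(membrane_burial(z = 0), 1)
  expect_equal(membrane_burial(z = c(-15, 15)), c(1, 1))
  expect_lt(membrane_burial(z = 40), 0.01)
  z <- seq(-30, 30, by = 0.25)
  w <- membrane_burial(z = z)
  expect_equal(w, rev(w))                       # slab symmetry
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w[z >= 0]) <= 1e-12))    # non-increasing in |z|
  # continuity at the core and solvent edges
  expect_equal(membrane_burial(z = 15 + 1e-9), 1, tolerance = 1e-6)
  expect_equal(membrane_burial(z = 20 - 1e-9), 0, tolerance = 1e-6)
  expect_equal(membrane_burial(z = 17.5), 0.5)  # half-cosine midpoint
})

test_that("functional density matches the hand-worked weighted average", {
  # neighbors at d = 2 (property 1.0) and d = 4 (property 0.0)
  tab <- load_property_table()
  tab[, "probe"] <- 0
  tab["W", "probe"] <- 1
  s <- structure_model(data.frame(position = 1:3, aa = c("A", "W", "G"),
                                  x = c(0, 2, 0), y = c(0, 0, 4),
                                  z = c(0, 0, 0)))
  expect_equal(functional_density(s, 1, "probe", radius = 6.5, table = tab),
               (1 / 2) / (1 / 2 + 1 / 4), tolerance = 1e-12)
})

test_that("functional density floors distances and falls back when alone", {
  tab <- load_property_table()
  # a neighbor at 0.4 A is weighted as if at the 1 A floor
  s <- structure_model(data.frame(position = 1:2, aa = c("A", "W"),
                                  x = c(0, 0.4), y = 0, z = 0))
  expect_equal(functional_density(s, 1, "vdw_volume", radius = 2),
               get_property("W", "vdw_volume"))
  # empty neighborhood -> property of the assumed (mutant) residue
  lone <- structure_model(data.frame(position = 1:2, aa = c("A", "W"),
                                     x = c(0, 50), y = 0, z = 0))
  expect_equal(functional_density(lone, 1, "vdw_volume", radius = 1,
                                  mutant_aa = "F"),
               get_property("F", "vdw_volume"))
})

test_that("functional density equals a brute-force oracle on point clouds", {
  tab <- load_property_table()
  for (seed in 1:5) {
    cloud <- random_cloud(50, seed = seed)
    for (p in sample(cloud$position, 4)) {
      for (r in c(1, 6.5, 12)) {
        expect_equal(functional_density(cloud, p, "hydrophobicity", r,
                                        mutant_aa = "K"),
                     fd_oracle(cloud, p, "hydrophobicity", r, "K", tab),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("neighbor vector handles the defined edge configurations", {
  # no neighbors in range -> fully exposed
  s <- structure_model(data.frame(position = 1:2, aa = "A",
                                  x = c(0, 30), y = 0, z = 0))
  expect_equal(neighbor_vector(s, 1), 1)
  # a perfectly symmetric octahedral shell cancels -> buried
  oct <- structure_model(data.frame(
    position = 1:7, aa = "A",
    x = c(0, 5, -5, 0, 0, 0, 0), y = c(0, 0, 0, 5, -5, 0, 0),
    z = c(0, 0, 0, 0, 0, 5, -5)))
  expect_equal(neighbor_vector(oct, 1), 0, tolerance = 1e-12)
  # exactly one neighbor at the inner bound -> unit vector, weight 1
  one <- structure_model(data.frame(position = 1:2, aa = "A",
                                    x = c(0, 3.3), y = 0, z = 0))
  expect_equal(neighbor_vector(one, 1), 1)
})

test_that("neighbor vector stays in [0,1] and matches its oracle", {
  for (seed in 1:20) {
    cloud <- random_cloud(30, seed = 100 + seed, box = 12)
    for (p in sample(cloud$position, 3)) {
      nv <- neighbor_vector(cloud, p)
      expect_gte(nv, 0); expect_lte(nv, 1)
      expect_equal(nv, nv_oracle(cloud, p), tolerance = 1e-9)
    }
  }
})

test_that("deleting neighbors exposes constructed one-sided sites", {
  # collinear neighbors: unit vectors identical, exposure is exactly 1
  # no matter how many are deleted
  ray <- data.frame(position = 1:4, aa = "A",
                    x = c(0, 4, 5, 6), y = 0, z = 0)
  for (k in 4:2) {
    expect_equal(neighbor_vector(structure_model(ray[1:k, ])
                                 , 1), 1, tolerance = 1e-12)
  }
  # a symmetric pair at +/- theta has exposure cos(theta); deleting one
  # member increases exposure to 1
  th <- pi / 5
  pair <- structure_model(data.frame(
    position = 1:3, aa = "A",
    x = c(0, 5 * cos(th), 5 * cos(th)),
    y = c(0, 5 * sin(th), -5 * sin(th)), z = 0))
  expect_equal(neighbor_vector(pair, 1), cos(th), tolerance = 1e-9)
  expect_gt(neighbor_vector(structure_model(pair[1:2, ]), 1),
            neighbor_vector(pair, 1))
})

test_that("a written bundle reads back identically through the PDB path", {
  s <- small_structure()
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, f)
  r <- read_structure(f)
  expect_equal(r$position, s$position)
  expect_equal(r$aa, s$aa)
  expect_equal(r$x, s$x, tolerance = 1e-6)
  expect_equal(r$y, s$y, tolerance = 1e-6)
  expect_equal(r$z, s$z, tolerance = 1e-6)
})

test_that("side-chain centroids are used with alpha-carbon fallback", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       3.000   0.000   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.000   2.000   0.000  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       4.000   0.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       5.000   1.000   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       6.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- read_structure(f)
  expect_equal(s$aa, c("A", "G"))
  expect_equal(c(s$x[1], s$y[1]), c(1, 2))   # CB centroid for Ala
  expect_equal(c(s$x[2], s$y[2]), c(5, 1))   # CA fallback for Gly
  s_ca <- read_structure(f, rep_point = "ca")
  expect_equal(s_ca$y[1], 0)
})
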