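test_that("distance measurement is Euclidean and symmetric", {
  m <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.54)))
  expect_equal(measure_distance(m, 1, 2), 1.54)
  expect_equal(measure_distance(m, 2, 1), measure_distance(m, 1, 2))
  expect_error(measure_distance(m, 1, 1), class = "molforge_bad_index")
  expect_error(measure_distance(m, 1, 9), class = "molforge_bad_index")
})

test_that("angles hit the tetrahedral ideal and degenerate limits", {
  m <- make_fixture("methane")
  expect_equal(measure_angle(m, 2, 1, 3), 180 / pi * acos(-1 / 3),
               tolerance = 1e-9)
  lin <- molecule(c("C", "C", "C"),
                  rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(measure_angle(lin, 1, 2, 3), 180)
  twin <- molecule(c("H", "C", "H"),
                   rbind(c(1, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_equal(measure_angle(twin, 1, 2, 3), 0)
  zero <- molecule(c("H", "H", "H"), rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(measure_angle(zero, 1, 2, 3),
               class = "molforge_degenerate_geometry")
})

test_that("dihedrals are signed and behave under mirroring", {
  eth <- make_fixture("ethane_staggered")
  expect_equal(measure_dihedral(eth, 3, 1, 2, 6), 180)
  ecl <- make_fixture("ethane_eclipsed")
  expect_equal(measure_dihedral(ecl, 3, 1, 2, 7), 0, tolerance = 1e-9)

  sb <- make_fixture("s_2_butanol")
  mir <- mirror_molecule(sb, "yz")
  for (quad in list(c(1, 2, 3, 4), c(5, 2, 3, 4), c(6, 2, 3, 4))) {
    expect_opposite_dihedral(
      measure_dihedral(mir, quad[1], quad[2], quad[3], quad[4]),
      measure_dihedral(sb, quad[1], quad[2], quad[3], quad[4]))
  }
  expect_error(measure_dihedral(eth, 3, 1, 2, 3), class = "molforge_bad_index")
})

test_that("rotations are rigid, periodic and compose additively", {
  sb <- make_fixture("s_2_butanol")
  full <- rotate_molecule(sb, 360, axis = "y")
  expect_equal(full$coords, sb$coords, tolerance = 1e-9)

  ab <- rotate_molecule(rotate_molecule(sb, 25, axis = "x"), 17, axis = "x")
  once <- rotate_molecule(sb, 42, axis = "x")
  expect_equal(ab$coords, once$coords, tolerance = 1e-9)

  rot <- rotate_molecule(sb, 33.3, axis = c(1, 2, -0.5))
  expect_equal(dist_matrix(rot), dist_matrix(sb), tolerance = 1e-9)
  expect_equal(rot$bonds, sb$bonds)
  expect_equal(measure_distance(rot, 1, 2), measure_distance(sb, 1, 2),
               tolerance = 1e-9)
})

test_that("subset rotation about a bond axis shifts dihedrals exactly", {
  eth <- make_fixture("ethane_staggered")
  before <- measure_dihedral(eth, 3, 1, 2, 6)
  moved <- rotate_molecule(eth, 60, axis = eth$coords[2, ] - eth$coords[1, ],
                           subset = c(2, 6, 7, 8), anchor = eth$coords[1, ])
  after <- measure_dihedral(moved, 3, 1, 2, 6)
  delta <- (after - before) %% 360
  expect_equal(min(delta, 360 - delta), 60, tolerance = 1e-9)
  # distances within the moved and fixed sets are untouched
  expect_equal(measure_distance(moved, 6, 7), measure_distance(eth, 6, 7),
               tolerance = 1e-9)
  expect_equal(measure_distance(moved, 3, 4), measure_distance(eth, 3, 4),
               tolerance = 1e-9)
})

test_that("mirroring is an involution and an isometry", {
  sb <- make_fixture("s_2_butanol")
  for (plane in c("xy", "xz", "yz")) {
    twice <- mirror_molecule(mirror_molecule(sb, plane), plane)
    expect_equal(twice$coords, sb$coords)
    expect_equal(dist_matrix(mirror_molecule(sb, plane)), dist_matrix(sb),
                 tolerance = 1e-12)
  }
})

test_that("molecular weight and heavy-atom listing", {
  m <- make_fixture("methane")
  expect_equal(molecular_weight(m), 16.043, tolerance = 0.01)
  expect_equal(molecular_weight(molecule()), 0)
  expect_equal(molecular_weight(rotate_molecule(m, 30, "z")),
               molecular_weight(m))

  expect_equal(heavy_atom_coordinates(m)$symbol, "C")
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.62)))
  expect_equal(nrow(heavy_atom_coordinates(h2)), 0)
  expect_equal(heavy_atom_coordinates(make_fixture("benzene"))$symbol,
               rep("C", 6))
})
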