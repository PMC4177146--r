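test_that("octet-rule hydrogen counts", {
  expect_equal(hydrogens_needed("C", 1), 3L)
  expect_equal(hydrogens_needed("N", 1), 2L)
  expect_equal(hydrogens_needed("O", 1), 1L)
  expect_equal(hydrogens_needed("F", 1), 0L)
  expect_equal(hydrogens_needed("Ne", 0), 0L)
  expect_equal(hydrogens_needed("Fe", 0), 0L) # d-block: no autocompletion
  # never exceeds three for any p-block element and bond count
  tab <- element_table()
  for (sym in tab$symbol[tab$block == "p"]) {
    for (b in 0:6) {
      h <- hydrogens_needed(sym, b)
      expect_gte(h, 0L)
      expect_lte(h, 3L)
    }
  }
})

test_that("change_element keeps coordinates for multiply-bonded atoms", {
  m <- make_fixture("methane")
  m2 <- change_element(m, 1, "N")
  expect_equal(m2$symbols[1], "N")
  expect_equal(m2$coords, m$coords)
  expect_equal(n_atoms(m2), 5)

  iso <- molecule("C", c(1, 2, 3))
  expect_equal(change_element(iso, 1, "Si")$symbols, "Si")
})

test_that("change_element repositions singly-bonded atoms and fills H", {
  hc <- molecule(c("H", "C"), rbind(c(0, 0, 0), c(0, 0, 1.07)),
                 bonds = rbind(c(1, 2)))
  out <- change_element(hc, 1, "O")
  expect_equal(n_atoms(out), 3) # O picked up one hydrogen
  expect_equal(measure_distance(out, 1, 2),
               covalent_radius("O") + covalent_radius("C"))
  # repositioned along the original bond direction (still on the z axis)
  expect_equal(unname(out$coords[1, 1:2]), c(0, 0), tolerance = 1e-9)
  expect_equal(measure_distance(out, 1, 3),
               covalent_radius("O") + covalent_radius("H"), tolerance = 1e-6)
  expect_equal(measure_angle(out, 2, 1, 3), hybridization("sp3")$ideal_angle,
               tolerance = 1e-6)
})

test_that("add_bonded_atom uses the open valence direction", {
  ch3 <- delete_atom(make_fixture("methane"), 5)
  out <- add_bonded_atom(ch3, 1, "C")
  new_c <- 5
  expect_equal(measure_distance(out, 1, new_c), 2 * covalent_radius("C"),
               tolerance = 1e-6)
  # the open tetrahedral direction makes ideal angles to the remaining H
  for (h in 2:4) {
    expect_equal(measure_angle(out, h, 1, new_c),
                 hybridization("sp3")$ideal_angle, tolerance = 1)
  }
  # the new carbon was autocompleted with three hydrogens of its own
  expect_equal(n_atoms(out), 8)
  expect_equal(sort(bonded_atoms(out, new_c)), c(1L, 6L, 7L, 8L))

  lone <- molecule("C", c(0, 0, 0))
  grown <- add_bonded_atom(lone, 1, "C")
  expect_equal(measure_distance(grown, 1, 2), 2 * covalent_radius("C"),
               tolerance = 1e-6)
})

test_that("add_hydrogen never moves existing atoms", {
  ch3 <- delete_atom(make_fixture("methane"), 5)
  out <- add_hydrogen(ch3, 1)
  expect_equal(out$coords[1:4, ], ch3$coords)
  expect_equal(measure_distance(out, 1, 5),
               covalent_radius("C") + covalent_radius("H"), tolerance = 1e-6)
  # lands within 5 degrees of the ideal fourth tetrahedral direction
  for (h in 2:4) {
    expect_equal(measure_angle(out, h, 1, 5),
                 hybridization("sp3")$ideal_angle, tolerance = 5)
  }
  bare <- molecule("O", c(0, 0, 0))
  grown <- add_hydrogen(bare, 1)
  expect_equal(measure_distance(grown, 1, 2),
               covalent_radius("O") + covalent_radius("H"), tolerance = 1e-6)
})

test_that("delete_atom removes attached hydrogens and compacts indices", {
  m <- make_fixture("methane")
  expect_equal(n_atoms(delete_atom(m, 1)), 0) # C and all 4 H go
  m2 <- delete_atom(m, 2)
  expect_equal(n_atoms(m2), 4)
  expect_equal(n_bonds(m2), 3)
  expect_true(validate_molecule_ok(m2))

  sb <- make_fixture("s_2_butanol")
  out <- delete_atom(sb, 5) # hydroxyl O takes its H along
  expect_equal(n_atoms(out), 13)
  expect_false("O" %in% out$symbols)
  # carbon skeleton intact: C2-C3 still bonded after re-indexing
  expect_equal(sum(out$symbols == "C"), 4)
  expect_true(validate_molecule_ok(out))
})

test_that("bond edits are pure connectivity changes", {
  m <- make_fixture("methane")
  plus <- add_bond(m, 2, 3)
  expect_equal(plus$coords, m$coords)
  back <- delete_bond(plus, 2, 3)
  expect_equal(back$bonds, m$bonds)
  expect_error(add_bond(m, 1, 1), class = "molforge_bad_index")
  expect_error(add_bond(m, 1, 2), class = "molforge_duplicate_bond")
  expect_error(delete_bond(m, 2, 3), class = "molforge_no_such_bond")

  # the zinc-blende trick: 12 hand-made edges outline the unit cell
  cube <- make_fixture("cube_corners")
  expect_equal(n_bonds(cube), 0)
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                 c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  for (k in seq_len(nrow(edges))) {
    cube <- add_bond(cube, edges[k, 1], edges[k, 2])
  }
  expect_equal(n_bonds(cube), 12)
  expect_equal(cube$coords, make_fixture("cube_corners")$coords)
})

test_that("fragment rotation turns dihedrals by the requested angle", {
  eth <- make_fixture("ethane_staggered")
  before <- sapply(6:8, function(h) measure_dihedral(eth, 3, 1, 2, h))
  out <- rotate_fragment(eth, 1, 2, 60)
  after <- sapply(6:8, function(h) measure_dihedral(out, 3, 1, 2, h))
  shift <- (after - before) %% 360
  expect_equal(pmin(shift, 360 - shift), rep(60, 3), tolerance = 1e-9)

  ident <- rotate_fragment(eth, 1, 2, 360)
  expect_equal(ident$coords, eth$coords, tolerance = 1e-9)

  expect_error(rotate_fragment(make_fixture("benzene"), 1, 2, 30),
               class = "molforge_ring_bond")
})

test_that("undo and redo walk the bounded snapshot stack", {
  h <- edit_history()
  m0 <- make_fixture("methane")
  m1 <- add_hydrogen(m0, 1, history = h)
  expect_true(can_undo(h))
  back <- undo(h, m1)
  expect_identical(back, m0)
  expect_true(can_redo(h))
  expect_identical(redo(h, back), m1)

  # a fresh edit clears the redo stack
  h2 <- edit_history()
  a <- add_hydrogen(m0, 1, history = h2)
  b <- undo(h2, a)
  add_hydrogen(b, 1, history = h2)
  expect_false(can_redo(h2))

  expect_warning(undo(edit_history(), m0), class = "molforge_empty_history")
})

test_that("exactly ten undos survive fifteen edits", {
  h <- edit_history()
  cur <- make_fixture("methane")
  for (k in 1:15) cur <- add_hydrogen(cur, 1, history = h)
  successes <- 0
  for (k in 1:15) {
    if (!can_undo(h)) break
    cur <- undo(h, cur)
    successes <- successes + 1
  }
  expect_equal(successes, 10)
  expect_warning(undo(h, cur), class = "molforge_empty_history")
})

test_that("folding undo over short random edit scripts restores the start", {
  set.seed(42)
  for (trial in 1:10) {
    start <- make_fixture("methane")
    n_edits <- sample(1:10, 1)
    script <- random_edit_script(start, n_edits)
    h <- edit_history()
    cur <- apply_edit_script(start, script, history = h)
    for (k in seq_len(n_edits)) cur <- undo(h, cur)
    expect_identical(cur, start)
    expect_false(can_undo(h))
  }
})

test_that("construction bond lengths equal the radii sum", {
  set.seed(7)
  m <- make_fixture("methane")
  for (trial in 1:10) {
    target <- sample(n_atoms(m), 1)
    sym <- sample(c("C", "N", "O", "Cl"), 1)
    grown <- add_bonded_atom(m, target, sym)
    new_idx <- n_atoms(m) + 1
    expect_equal(measure_distance(grown, target, new_idx),
                 covalent_radius(m$symbols[target]) + covalent_radius(sym),
                 tolerance = 1e-6)
    m2 <- add_hydrogen(m, target)
    expect_equal(measure_distance(m2, target, n_atoms(m2)),
                 covalent_radius(m$symbols[target]) + covalent_radius("H"),
                 tolerance = 1e-6)
    expect_true(validate_molecule_ok(grown))
  }
})

test_that("edit scripts parse and dispatch", {
  m <- make_fixture("methane")
  out <- apply_edit_script(m, c("# grow then prune", "addh 1", "undo",
                                "chelem 1 n", "delatom 5"))
  expect_equal(out$symbols[1], "N")
  expect_equal(n_atoms(out), 4)
  expect_error(apply_edit_script(m, "bogus 1"), class = "molforge_parse_error")
  expect_error(apply_edit_script(m, "addbond 1"), class = "molforge_parse_error")
})
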