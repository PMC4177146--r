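# Shared helpers: an independent O(n^2) bond oracle, SVG introspection via
# xml2, and a generator of random-but-valid edit scripts.

# Reference bond perception: explicit double loop over all pairs, written
# independently of perceive_bonds() and kept deliberately naive.
oracle_bonds <- function(mol, factor = 1.2) {
  n <- n_atoms(mol)
  r <- covalent_radius(mol$symbols)
  out <- matrix(integer(), 0, 2)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
      if (d < factor * (r[i] + r[j])) out <- rbind(out, c(i, j))
    }
  }
  out
}

expect_same_bonds <- function(mol, expected) {
  got <- mol$bonds
  dimnames(got) <- NULL
  dimnames(expected) <- NULL
  expect_equal(got, matrix(as.integer(expected), ncol = 2))
}

svg_circles <- function(svg) {
  doc <- xml2::read_xml(svg)
  xml2::xml_find_all(doc, ".//*[local-name()='circle'][@data-atom]")
}

svg_lines <- function(svg) {
  doc <- xml2::read_xml(svg)
  xml2::xml_find_all(doc, ".//*[local-name()='line']")
}

svg_has_gradients <- function(svg) {
  grepl("<radialGradient", svg, fixed = TRUE)
}

# Random edit scripts built only from always-valid operations, so any
# prefix can be undone snapshot by snapshot.
random_edit_script <- function(mol, n_edits) {
  lines <- character(n_edits)
  n <- n_atoms(mol)
  for (k in seq_len(n_edits)) {
    op <- sample(c("addh", "addatom", "chelem"), 1)
    target <- sample(n, 1)
    lines[k] <- switch(op,
      addh = sprintf("addh %d", target),
      addatom = { n <- n + 1 + hydrogens_needed("C", 1) # C brings 3 H
                  sprintf("addatom %d C", target) },
      chelem = sprintf("chelem 1 %s", sample(c("C", "N", "Si"), 1))
    )
    if (op == "addh") n <- n + 1
  }
  lines
}

dist_matrix <- function(mol) as.matrix(stats::dist(mol$coords))

# Sign flip modulo the (-180, 180] branch cut: a and -b describe the same
# torsion when their sum is a multiple of 360.
expect_opposite_dihedral <- function(a, b, tol = 1e-9) {
  wrapped <- ((a + b + 180) %% 360) - 180
  expect_equal(wrapped, 0, tolerance = tol)
}

# Distance from a dihedral to the nearest staggered value {..., -60, 60, 180}
staggered_distance <- function(phi) {
  d <- (phi - 60) %% 120
  min(d, 120 - d)
}

validate_molecule_ok <- function(mol) {
  molforge:::validate_molecule(mol)
  TRUE
}
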