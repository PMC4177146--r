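# Distance-based bond perception and graph queries on the bond set.
#
# The perception rule: atoms i and j are bonded iff
#   ||p_i - p_j|| < factor * (r_i + r_j),
# with strict inequality and factor defaulting to 1.2. A pair exactly at
# the cutoff is NOT bonded. Ring membership is answered per query by
# checking connectivity after removing the edge — molecules here are small,
# so no ring-set precomputation is worthwhile.

#' Perceive bonds from interatomic distances
#'
#' Replaces the molecule's bond set: every pair of atoms closer than
#' `factor` times the sum of their covalent radii becomes a bond. All pairs
#' are examined; the comparison is strictly "less than".
#'
#' @param mol A [molecule()].
#' @param factor Dimensionless multiplier on the radii sum (default 1.2).
#' @return The molecule with its bond set replaced.
#' @export
#' @examples
#' m <- make_fixture("methane")
#' n_bonds(perceive_bonds(m)) # 4
perceive_bonds <- function(mol, factor = 1.2) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  n <- n_atoms(mol)
  if (n < 2) {
    mol$bonds <- canonical_bonds(NULL, n)
    return(mol)
  }
  r <- covalent_radius(mol$symbols)
  d <- as.matrix(stats::dist(mol$coords))
  cutoff <- factor * outer(r, r, "+")
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- canonical_bonds(hit, n)
  mol
}

# igraph wants the vertex count explicit so isolated atoms stay vertices
bond_graph <- function(mol, drop_bond = NULL) {
  b <- mol$bonds
  if (!is.null(drop_bond)) {
    lo <- min(drop_bond); hi <- max(drop_bond)
    b <- b[!(b[, 1] == lo & b[, 2] == hi), , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(b) > 0) g <- igraph::add_edges(g, t(b))
  g
}

require_bond <- function(mol, i, j) {
  i <- check_atom_index(mol, i)
  j <- check_atom_index(mol, j)
  if (!has_bond(mol, i, j)) {
    mf_stop(sprintf("no bond between atoms %d and %d", i, j), "no_such_bond")
  }
  c(min(i, j), max(i, j))
}

#' Does a bond lie on a ring?
#'
#' A bond is part of a ring exactly when removing it leaves its endpoints
#' connected by some other path.
#'
#' @param mol A [molecule()].
#' @param i,j Atom indices of an existing bond.
#' @return `TRUE` if the bond lies on a cycle.
#' @export
bond_in_ring <- function(mol, i, j) {
  b <- require_bond(mol, i, j)
  g <- bond_graph(mol, drop_bond = b)
  comp <- igraph::components(g)$membership
  comp[b[1]] == comp[b[2]]
}

#' Split a molecule at a non-ring bond
#'
#' Removes the bond and returns the two connected components containing its
#' endpoints. Only meaningful for acyclic (non-ring) bonds; a ring bond is
#' an error since removing it does not disconnect anything.
#'
#' @param mol A [molecule()].
#' @param i,j Atom indices of an existing, non-ring bond.
#' @return List with integer index vectors `side_i` and `side_j` (each
#'   sorted, containing its endpoint).
#' @export
#' @examples
#' eth <- make_fixture("ethane_staggered")
#' split_by_bond(eth, 1, 2)
split_by_bond <- function(mol, i, j) {
  b <- require_bond(mol, i, j)
  if (bond_in_ring(mol, i, j)) {
    mf_stop(sprintf("bond %d-%d is part of a ring and cannot split the molecule",
                    b[1], b[2]), "ring_bond")
  }
  comp <- igraph::components(bond_graph(mol, drop_bond = b))$membership
  list(side_i = sort(which(comp == comp[as.integer(i)])),
       side_j = sort(which(comp == comp[as.integer(j)])))
}
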