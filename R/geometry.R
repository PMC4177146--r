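# Measurement and rigid-body transformations. Angles are reported in
# degrees (chemistry convention); internals work in radians. Rotations use
# the Rodrigues formula about an arbitrary unit axis.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v, context = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) {
    mf_stop(sprintf("degenerate geometry: zero-length %s", context),
            "degenerate_geometry")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix: right-handed rotation by theta (radians)
# about the unit axis.
rotation_matrix <- function(axis, theta) {
  u <- unit_vector(axis, "rotation axis")
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

#' Distance between two atoms
#'
#' @param mol A [molecule()].
#' @param i,j Distinct atom indices.
#' @return Euclidean distance in Angstrom.
#' @export
measure_distance <- function(mol, i, j) {
  i <- check_atom_index(mol, i); j <- check_atom_index(mol, j)
  if (i == j) mf_stop("distance requires two distinct atoms", "bad_index")
  vnorm(mol$coords[i, ] - mol$coords[j, ])
}

#' Angle at a vertex atom
#'
#' The angle between the vectors j->i and j->k, in degrees. The normalized
#' dot product is clamped to \[-1, 1\] before the arc-cosine so that ideal
#' linear or coincident arms do not produce NaN.
#'
#' @param mol A [molecule()].
#' @param i,j,k Distinct atom indices; `j` is the vertex.
#' @return Angle in degrees, in \[0, 180\].
#' @export
measure_angle <- function(mol, i, j, k) {
  i <- check_atom_index(mol, i); j <- check_atom_index(mol, j)
  k <- check_atom_index(mol, k)
  if (anyDuplicated(c(i, j, k))) {
    mf_stop("angle requires three distinct atoms", "bad_index")
  }
  u <- unit_vector(mol$coords[i, ] - mol$coords[j, ], "angle arm j-i")
  v <- unit_vector(mol$coords[k, ] - mol$coords[j, ], "angle arm j-k")
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed dihedral (torsion) angle
#'
#' The torsion between planes (i, j, k) and (j, k, l), signed by the
#' right-hand rule about the j->k axis.
#'
#' @param mol A [molecule()].
#' @param i,j,k,l Four distinct atom indices.
#' @return Angle in degrees, in (-180, 180\].
#' @export
measure_dihedral <- function(mol, i, j, k, l) {
  idx <- vapply(list(i, j, k, l), function(a) check_atom_index(mol, a), 1L)
  if (anyDuplicated(idx)) {
    mf_stop("dihedral requires four distinct atoms", "bad_index")
  }
  p <- mol$coords[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12) {
    mf_stop("degenerate geometry: collinear atoms in dihedral",
            "degenerate_geometry")
  }
  m1 <- cross3(n1, unit_vector(b2, "dihedral axis"))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  deg <- rad2deg(ang)
  if (deg <= -180) deg <- deg + 360
  deg
}

#' Rotate a molecule or a subset of its atoms
#'
#' For a Cartesian axis (`"x"`, `"y"`, `"z"`) the pivot defaults to the
#' centroid of the whole molecule; for a numeric axis vector an `anchor`
#' point on the axis may be supplied (default: centroid). Only atoms in
#' `subset` move; all pairwise distances within the moved set and within
#' the fixed set are preserved.
#'
#' @param mol A [molecule()].
#' @param angle Rotation angle in degrees (right-handed about the axis).
#' @param axis `"x"`, `"y"`, `"z"`, or a numeric length-3 direction vector.
#' @param subset Atom indices to move; `NULL` means all atoms.
#' @param anchor Point on the rotation axis; `NULL` means the molecule
#'   centroid.
#' @return The rotated molecule.
#' @export
rotate_molecule <- function(mol, angle, axis = "z", subset = NULL,
                            anchor = NULL) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  stopifnot(is.numeric(axis), length(axis) == 3)
  if (n_atoms(mol) == 0) return(mol)
  if (is.null(anchor)) anchor <- colMeans(mol$coords)
  subset <- if (is.null(subset)) seq_len(n_atoms(mol)) else
    check_atom_index(mol, subset)
  rot <- rotation_matrix(axis, deg2rad(angle))
  moved <- sweep(mol$coords[subset, , drop = FALSE], 2, anchor)
  mol$coords[subset, ] <- sweep(moved %*% t(rot), 2, anchor, "+")
  mol
}

#' Translate a molecule or a subset of its atoms
#'
#' @param mol A [molecule()].
#' @param offset Numeric length-3 displacement in Angstrom.
#' @param subset Atom indices to move; `NULL` means all atoms.
#' @return The translated molecule.
#' @export
translate_molecule <- function(mol, offset, subset = NULL) {
  stopifnot(is.numeric(offset), length(offset) == 3)
  subset <- if (is.null(subset)) seq_len(n_atoms(mol)) else
    check_atom_index(mol, subset)
  mol$coords[subset, ] <- sweep(mol$coords[subset, , drop = FALSE], 2,
                                offset, "+")
  mol
}

#' Mirror a molecule through a coordinate plane
#'
#' Negates the coordinate normal to the chosen plane for every atom; bonds
#' are unchanged. An improper isometry: distances and unsigned angles are
#' preserved, every signed dihedral changes sign — mirroring a chiral
#' molecule yields its enantiomer.
#'
#' @param mol A [molecule()].
#' @param plane One of `"xy"`, `"xz"`, `"yz"`.
#' @return The mirrored molecule.
#' @export
mirror_molecule <- function(mol, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  col <- switch(plane, xy = 3, xz = 2, yz = 1)
  mol$coords[, col] <- -mol$coords[, col]
  mol
}

#' Molecular weight
#'
#' @param mol A [molecule()].
#' @return Sum of atomic masses in u (0 for an empty molecule).
#' @export
molecular_weight <- function(mol) {
  if (n_atoms(mol) == 0) return(0)
  sum(atomic_mass(mol$symbols))
}

#' Coordinates of all non-hydrogen atoms
#'
#' @param mol A [molecule()].
#' @return Data frame with columns `index`, `symbol`, `x`, `y`, `z`, in the
#'   original atom order.
#' @export
heavy_atom_coordinates <- function(mol) {
  keep <- which(mol$symbols != "H")
  data.frame(index = keep,
             symbol = mol$symbols[keep],
             x = mol$coords[keep, 1],
             y = mol$coords[keep, 2],
             z = mol$coords[keep, 3],
             row.names = NULL)
}
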