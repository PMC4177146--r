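# Crude VSEPR-style geometry clean-up. Not molecular mechanics: each
# iteration applies three damped correction passes —
#   (a) every bond length toward the sum of covalent radii,
#   (b) every bond angle toward the center atom's hybridization ideal,
#   (c) every rotatable (non-ring) bond's torsion toward staggered
#       (dihedrals at 60 degree offsets),
# until the largest per-atom displacement in an iteration drops below the
# coordinate tolerance or the iteration cap is hit. Pass order and
# atom-index order within passes are fixed, so the routine is
# deterministic. Connectivity is never altered.

#' Optimizer settings
#'
#' @param max_iterations Iteration cap (default 200).
#' @param coordinate_tolerance Convergence threshold in Angstrom on the
#'   maximum per-atom displacement within one iteration (default 1e-4).
#' @param step_fraction Fraction of each ideal correction applied per
#'   iteration, in (0, 1\] (default 0.5); damping keeps the interacting
#'   passes stable.
#' @return A list of validated settings.
#' @export
optimize_settings <- function(max_iterations = 200,
                              coordinate_tolerance = 1e-4,
                              step_fraction = 0.5) {
  stopifnot(max_iterations >= 1, coordinate_tolerance > 0,
            step_fraction > 0, step_fraction <= 1)
  list(max_iterations = as.integer(max_iterations),
       coordinate_tolerance = coordinate_tolerance,
       step_fraction = step_fraction)
}

# Per-atom hybridization vector, defaulting to sp3 where unassigned.
resolve_hybridizations <- function(mol, hyb) {
  n <- n_atoms(mol)
  kinds <- rep("sp3", n)
  if (is.null(hyb)) return(kinds)
  if (is.character(hyb) && length(hyb) == 1 && is.null(names(hyb))) {
    return(rep(match.arg(hyb, c("sp3", "sp2", "sp")), n))
  }
  idx <- as.integer(names(hyb))
  if (any(is.na(idx))) {
    mf_stop("hybridization assignments must be named by atom index",
            "bad_index")
  }
  check_atom_index(mol, idx, "hybridization atom index")
  kinds[idx] <- vapply(unname(hyb), function(k) {
    match.arg(k, c("sp3", "sp2", "sp"))
  }, character(1))
  kinds
}

# All (i, center, k) angle triples over the bond set.
angle_triples <- function(mol) {
  out <- list()
  for (j in seq_len(n_atoms(mol))) {
    nb <- bonded_atoms(mol, j)
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    out[[length(out) + 1]] <- cbind(pairs[1, ], j, pairs[2, ])
  }
  if (length(out) == 0) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

# Surrogate objective: squared bond-length error (Angstrom^2) plus squared
# angle error (radians^2). Used for the monotone-descent diagnostic, not
# as a gradient.
surrogate_energy <- function(mol, kinds) {
  e <- 0
  b <- mol$bonds
  if (nrow(b) > 0) {
    r <- covalent_radius(mol$symbols)
    for (k in seq_len(nrow(b))) {
      len <- measure_distance(mol, b[k, 1], b[k, 2])
      e <- e + (len - (r[b[k, 1]] + r[b[k, 2]]))^2
    }
  }
  tri <- angle_triples(mol)
  for (k in seq_len(nrow(tri))) {
    th <- measure_angle(mol, tri[k, 1], tri[k, 2], tri[k, 3])
    ideal <- hybridization(kinds[tri[k, 2]])$ideal_angle
    e <- e + deg2rad(th - ideal)^2
  }
  e
}

bond_length_pass <- function(mol, step) {
  r <- covalent_radius(mol$symbols)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    v <- mol$coords[j, ] - mol$coords[i, ]
    len <- vnorm(v)
    if (len < 1e-9) next
    u <- v / len
    d <- step * ((r[i] + r[j]) - len)
    mol$coords[i, ] <- mol$coords[i, ] - u * d / 2
    mol$coords[j, ] <- mol$coords[j, ] + u * d / 2
  }
  mol
}

angle_pass <- function(mol, kinds, step) {
  tri <- angle_triples(mol)
  for (k in seq_len(nrow(tri))) {
    i <- tri[k, 1]; j <- tri[k, 2]; kk <- tri[k, 3]
    u <- mol$coords[i, ] - mol$coords[j, ]
    v <- mol$coords[kk, ] - mol$coords[j, ]
    if (vnorm(u) < 1e-9 || vnorm(v) < 1e-9) next
    w <- cross3(u / vnorm(u), v / vnorm(v))
    if (vnorm(w) < 1e-9) next # collinear: rotation plane undefined
    th <- measure_angle(mol, i, j, kk)
    ideal <- hybridization(kinds[j])$ideal_angle
    delta <- deg2rad(step * (ideal - th))
    # rotating u toward v is a +rotation about w; push arms apart by
    # rotating i by -delta/2 and k by +delta/2
    ri <- rotation_matrix(w, -delta / 2)
    rk <- rotation_matrix(w, +delta / 2)
    mol$coords[i, ] <- mol$coords[j, ] + as.numeric(ri %*% u)
    mol$coords[kk, ] <- mol$coords[j, ] + as.numeric(rk %*% v)
  }
  mol
}

# Smallest signed offset from phi to the staggered grid {..., -60, 60, 180}.
staggered_offset <- function(phi) {
  target <- 60 + 120 * round((phi - 60) / 120)
  target - phi
}

torsion_pass <- function(mol, step) {
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    si <- setdiff(bonded_atoms(mol, i), j)
    sj <- setdiff(bonded_atoms(mol, j), i)
    if (length(si) == 0 || length(sj) == 0) next
    if (bond_in_ring(mol, i, j)) next
    phi <- tryCatch(measure_dihedral(mol, si[1], i, j, sj[1]),
                    molforge_degenerate_geometry = function(e) NULL)
    if (is.null(phi)) next
    delta <- step * staggered_offset(phi)
    if (abs(delta) < 1e-12) next
    parts <- split_by_bond(mol, i, j)
    # right-hand rotation of the j-side fragment about i->j by +a shifts
    # the (si, i, j, sj) dihedral by -a (verified on the ethane fixture)
    if (length(parts$side_j) <= length(parts$side_i)) {
      mol <- rotate_molecule(mol, -delta, axis = mol$coords[j, ] - mol$coords[i, ],
                             subset = parts$side_j, anchor = mol$coords[i, ])
    } else {
      mol <- rotate_molecule(mol, delta, axis = mol$coords[j, ] - mol$coords[i, ],
                             subset = parts$side_i, anchor = mol$coords[j, ])
    }
  }
  mol
}

#' Crude VSEPR-style geometry optimization
#'
#' Iteratively relaxes bond lengths toward covalent-radii sums, bond angles
#' toward the per-atom hybridization ideal (sp3 109.471, sp2 120, sp 180
#' degrees) and rotatable-bond torsions toward staggered conformations.
#' This is a geometry clean-up in the spirit of a drawing tool, not a force
#' field: there are no nonbonded terms, and ring strain is handled only by
#' the angle pass (ring bonds are excluded from the torsion pass).
#'
#' @param mol A [molecule()] with at least one atom and its bonds assigned.
#' @param settings See [optimize_settings()].
#' @param hyb Per-atom hybridization: `NULL` (all sp3), a single kind, or a
#'   character vector named by atom index, e.g. `c("2" = "sp2")`.
#' @return A list with `molecule`, `iterations`, `converged`, and `energy`
#'   (the surrogate objective before iteration 1 and after each iteration).
#' @export
#' @examples
#' m <- make_fixture("methane", perturb = 0.1, seed = 1)
#' res <- optimize_geometry(m)
#' res$converged
optimize_geometry <- function(mol, settings = optimize_settings(),
                              hyb = NULL) {
  if (n_atoms(mol) == 0) {
    mf_stop("cannot optimize an empty molecule", "bad_index")
  }
  kinds <- resolve_hybridizations(mol, hyb)
  step <- settings$step_fraction
  energy <- surrogate_energy(mol, kinds)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(settings$max_iterations)) {
    before <- mol$coords
    mol <- bond_length_pass(mol, step)
    mol <- angle_pass(mol, kinds, step)
    mol <- torsion_pass(mol, step)
    iterations <- it
    energy <- c(energy, surrogate_energy(mol, kinds))
    moved <- sqrt(rowSums((mol$coords - before)^2))
    if (max(moved) < settings$coordinate_tolerance) {
      converged <- TRUE
      break
    }
  }
  list(molecule = mol, iterations = iterations, converged = converged,
       energy = energy)
}
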