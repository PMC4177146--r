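# Programmatic ideal-geometry test molecules. All bonded distances are
# built from the SHIPPED covalent-radii table (bond length = radii sum), so
# bond-perception and optimizer tests are self-consistent with whatever
# radii compilation the element table carries.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

tetra_angle <- function() rad2deg(acos(-1 / 3))

# Hydrogens around a carbon chain atom: directions at the tetrahedral angle
# from the `axis` direction, at the given azimuths (degrees) measured in
# the plane perpendicular to axis from a deterministic reference.
cone_directions <- function(axis, cone_angle_deg, azimuths_deg) {
  u <- unit_vector(axis, "cone axis")
  ref <- cross3(u, c(0, 0, 1))
  if (vnorm(ref) < 1e-6) ref <- cross3(u, c(1, 0, 0))
  ref <- ref / vnorm(ref)
  ref2 <- cross3(u, ref)
  ca <- cos(deg2rad(cone_angle_deg)); sa <- sin(deg2rad(cone_angle_deg))
  t(vapply(azimuths_deg, function(phi) {
    p <- deg2rad(phi)
    ca * u + sa * (cos(p) * ref + sin(p) * ref2)
  }, numeric(3)))
}

ethane_fixture <- function(staggered = TRUE) {
  rC <- covalent_radius("C"); rH <- covalent_radius("H")
  dCC <- 2 * rC; dCH <- rC + rH
  c1 <- c(0, 0, 0); c2 <- c(0, 0, dCC)
  h1 <- sweep(cone_directions(c(0, 0, 1), tetra_angle(),
                              c(0, 120, 240)) * dCH, 2, c1, "+")
  az2 <- if (staggered) c(0, 120, 240) else c(60, 180, 300)
  h2 <- sweep(cone_directions(c(0, 0, -1), tetra_angle(), -az2) * dCH,
              2, c2, "+")
  molecule(c("C", "C", rep("H", 6)), rbind(c1, c2, h1, h2),
           bonds = rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                         c(2, 6), c(2, 7), c(2, 8)),
           title = if (staggered) "ethane (staggered)" else "ethane (eclipsed)")
}

s_2_butanol_fixture <- function() {
  rC <- covalent_radius("C"); rH <- covalent_radius("H")
  rO <- covalent_radius("O")
  t4 <- ideal_directions("sp3")
  c2 <- c(0, 0, 0)
  # substituent layout chosen so that CIP priorities O > C3 > C1 > H trace
  # counterclockwise viewed from the side opposite H: the S enantiomer
  c1 <- 2 * rC * t4[2, ]        # methyl carbon
  c3 <- 2 * rC * t4[1, ]        # methylene carbon
  o  <- (rC + rO) * t4[3, ]     # hydroxyl oxygen
  h2 <- (rC + rH) * t4[4, ]     # stereocenter hydrogen
  place <- function(center, toward, k, len) {
    # k directions from `center`, tetrahedrally arranged away from `toward`
    rot <- alignment_rotation(t4[1, ], unit_vector(toward - center, "bond"))
    aligned <- t4 %*% t(rot)
    sweep(aligned[1 + seq_len(k), , drop = FALSE] * len, 2, center, "+")
  }
  h_c1 <- place(c1, c2, 3, rC + rH)
  rotc3 <- alignment_rotation(t4[1, ], unit_vector(c2 - c3, "bond"))
  dirs3 <- (t4 %*% t(rotc3))[2:4, , drop = FALSE]
  c4 <- c3 + 2 * rC * dirs3[1, ]
  h_c3 <- sweep(dirs3[2:3, , drop = FALSE] * (rC + rH), 2, c3, "+")
  h_c4 <- place(c4, c3, 3, rC + rH)
  h_o <- place(o, c2, 1, rO + rH)
  syms <- c("C", "C", "C", "C", "O", "H", "H", "H", "H", "H", "H", "H",
            "H", "H", "H")
  coords <- rbind(c1, c2, c3, c4, o, h2, h_c1, h_c3, h_c4, h_o)
  molecule(syms, coords,
           bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5), c(2, 6),
                         c(1, 7), c(1, 8), c(1, 9), c(3, 10), c(3, 11),
                         c(4, 12), c(4, 13), c(4, 14), c(5, 15)),
           title = "S-2-butanol")
}

#' Construct a named test molecule
#'
#' Deterministic, ideal-geometry fixtures built from the shipped
#' covalent-radii table:
#'
#' * `methane` — C plus 4 H at exact tetrahedral directions, C-H = radii sum.
#' * `ethane_staggered`, `ethane_eclipsed` — H-C-C-H dihedrals at
#'   \{60, 180, -60\} or \{0, 120, -120\} degrees.
#' * `benzene` — planar regular hexagon of carbons (C-C = radii sum) with
#'   radial hydrogens; connectivity only, no bond orders.
#' * `methylcyclohexane_skeleton` — the 7 heavy carbons of
#'   methylcyclohexane as a planar hexagon plus one exocyclic carbon
#'   (a ring-membership test graph, not a realistic conformation).
#' * `s_2_butanol` — CH3-CH(OH)-CH2-CH3 with the S configuration at C2.
#' * `cube_corners` — 8 zinc atoms at the vertices of a cube (edge 5.41
#'   Angstrom, the zinc-blende unit cell); no atoms within bonding range,
#'   bonds are added by hand to outline the cell.
#' * `random_cloud` — `n` carbons uniform in a 4 Angstrom box, seeded.
#'
#' @param name Fixture name (see above).
#' @param n Atom count for `random_cloud` (default 12); ignored otherwise.
#' @param seed Integer seed, required for `random_cloud` and whenever
#'   `perturb > 0`.
#' @param perturb Standard deviation (Angstrom) of seeded Gaussian noise
#'   added to every coordinate (default 0, exact geometry).
#' @return A [molecule()] with its bond set populated.
#' @export
#' @examples
#' make_fixture("methane")
#' make_fixture("random_cloud", n = 12, seed = 7)
make_fixture <- function(name, n = 12, seed = NULL, perturb = 0) {
  rC <- covalent_radius("C"); rH <- covalent_radius("H")
  mol <- switch(name,
    methane = {
      dirs <- ideal_directions("sp3")
      molecule(c("C", rep("H", 4)),
               rbind(c(0, 0, 0), dirs * (rC + rH)),
               bonds = cbind(1, 2:5), title = "methane")
    },
    ethane_staggered = ethane_fixture(TRUE),
    ethane_eclipsed = ethane_fixture(FALSE),
    benzene = {
      d <- 2 * rC # hexagon side == circumradius
      ang <- deg2rad(60 * (0:5))
      cpos <- cbind(d * cos(ang), d * sin(ang), 0)
      hpos <- cbind((d + rC + rH) * cos(ang), (d + rC + rH) * sin(ang), 0)
      ring <- cbind(1:6, c(2:6, 1))
      molecule(c(rep("C", 6), rep("H", 6)), rbind(cpos, hpos),
               bonds = rbind(ring, cbind(1:6, 7:12)), title = "benzene")
    },
    methylcyclohexane_skeleton = {
      d <- 2 * rC
      ang <- deg2rad(60 * (0:5))
      cpos <- cbind(d * cos(ang), d * sin(ang), 0)
      methyl <- c(2 * d, 0, 0)
      molecule(rep("C", 7), rbind(cpos, methyl),
               bonds = rbind(cbind(1:6, c(2:6, 1)), c(1, 7)),
               title = "methylcyclohexane (heavy atoms)")
    },
    s_2_butanol = s_2_butanol_fixture(),
    cube_corners = {
      a <- 5.41
      v <- as.matrix(expand.grid(x = c(0, a), y = c(0, a), z = c(0, a)))
      molecule(rep("Zn", 8), v, title = "cube corners (zinc-blende cell)")
    },
    random_cloud = {
      if (is.null(seed)) mf_stop("random_cloud requires a seed", "parse_error")
      coords <- with_seed(seed, matrix(stats::runif(n * 3, 0, 4), n, 3))
      m <- molecule(rep("C", n), coords,
                    title = sprintf("random cloud n=%d seed=%d", n, seed))
      perceive_bonds(m)
    },
    mf_stop(sprintf("unknown fixture: '%s'", name), "unknown_fixture")
  )
  if (perturb > 0) {
    if (is.null(seed)) mf_stop("perturbation requires a seed", "parse_error")
    noise <- with_seed(seed + 1L,
                       matrix(stats::rnorm(3 * n_atoms(mol), 0, perturb),
                              n_atoms(mol), 3))
    mol$coords <- mol$coords + noise
  }
  mol
}
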