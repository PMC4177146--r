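# Structure editing: add/change/delete atoms and bonds, octet-rule
# hydrogen autocompletion, fragment rotation about non-ring bonds, and a
# bounded snapshot stack for undo/redo.
#
# Every editing operation takes an optional `history`; when supplied, the
# pre-edit molecule is pushed onto the undo stack (evicting the oldest
# snapshot beyond capacity) and the redo stack is cleared.

#' Hybridization descriptor
#'
#' Maps the user-selectable hybridization to its ideal VSEPR bond angle and
#' maximum neighbor count: sp3 -> 109.471 deg (arccos(-1/3)) / 4, sp2 ->
#' 120 deg / 3, sp -> 180 deg / 2. The package default everywhere is sp3.
#'
#' @param kind One of `"sp3"`, `"sp2"`, `"sp"`.
#' @return List with `kind`, `ideal_angle` (degrees) and `max_neighbors`.
#' @export
#' @examples
#' hybridization("sp2")$ideal_angle # 120
hybridization <- function(kind = c("sp3", "sp2", "sp")) {
  kind <- match.arg(kind)
  switch(kind,
         sp3 = list(kind = "sp3", ideal_angle = rad2deg(acos(-1 / 3)),
                    max_neighbors = 4L),
         sp2 = list(kind = "sp2", ideal_angle = 120, max_neighbors = 3L),
         sp  = list(kind = "sp", ideal_angle = 180, max_neighbors = 2L))
}

# Ideal unit direction sets for each hybridization, in a canonical frame.
ideal_directions <- function(kind) {
  switch(kind,
         sp3 = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
           sqrt(3),
         sp2 = rbind(c(1, 0, 0), c(-1 / 2, sqrt(3) / 2, 0),
                     c(-1 / 2, -sqrt(3) / 2, 0)),
         sp  = rbind(c(1, 0, 0), c(-1, 0, 0)))
}

# Rotation taking unit vector a onto unit vector b (deterministic choice
# of perpendicular when a == -b).
alignment_rotation <- function(a, b) {
  d <- max(-1, min(1, sum(a * b)))
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    perp <- cross3(a, c(0, 0, 1))
    if (vnorm(perp) < 1e-6) perp <- cross3(a, c(1, 0, 0))
    return(rotation_matrix(perp, pi))
  }
  rotation_matrix(cross3(a, b), acos(d))
}

#' Create an edit history
#'
#' A bounded snapshot stack: the most recent `capacity` pre-edit states are
#' retained for undo, and undone states for redo. Any new edit clears the
#' redo stack. The history is an environment and is mutated in place by
#' the editing functions.
#'
#' @param capacity Maximum number of retained snapshots (default 10).
#' @return An object of class `edit_history`.
#' @export
edit_history <- function(capacity = 10) {
  stopifnot(capacity >= 1)
  h <- new.env(parent = emptyenv())
  h$undo <- list()
  h$redo <- list()
  h$capacity <- as.integer(capacity)
  class(h) <- "edit_history"
  h
}

#' @export
print.edit_history <- function(x, ...) {
  cat(sprintf("<edit_history> %d undo / %d redo (capacity %d)\n",
              length(x$undo), length(x$redo), x$capacity))
  invisible(x)
}

#' @rdname edit_history
#' @param history An [edit_history()].
#' @export
can_undo <- function(history) length(history$undo) > 0

#' @rdname edit_history
#' @export
can_redo <- function(history) length(history$redo) > 0

record_edit <- function(history, mol) {
  if (is.null(history)) return(invisible(NULL))
  stopifnot(inherits(history, "edit_history"))
  history$undo <- c(history$undo, list(mol))
  if (length(history$undo) > history$capacity) {
    history$undo <- history$undo[-1]
  }
  history$redo <- list()
  invisible(NULL)
}

#' Undo or redo an edit
#'
#' `undo()` restores the most recent snapshot, pushing the current state
#' onto the redo stack; `redo()` reverses an undo. With an empty stack the
#' molecule is returned unchanged and a classed warning
#' (`molforge_empty_history`) is signalled.
#'
#' @param history An [edit_history()].
#' @param mol The current [molecule()].
#' @return The restored molecule (or `mol` unchanged on an empty stack).
#' @export
undo <- function(history, mol) {
  stopifnot(inherits(history, "edit_history"))
  if (!can_undo(history)) {
    mf_warn("nothing to undo", "empty_history")
    return(mol)
  }
  prev <- history$undo[[length(history$undo)]]
  history$undo <- history$undo[-length(history$undo)]
  history$redo <- c(history$redo, list(mol))
  if (length(history$redo) > history$capacity) {
    history$redo <- history$redo[-1]
  }
  prev
}

#' @rdname undo
#' @export
redo <- function(history, mol) {
  stopifnot(inherits(history, "edit_history"))
  if (!can_redo(history)) {
    mf_warn("nothing to redo", "empty_history")
    return(mol)
  }
  nxt <- history$redo[[length(history$redo)]]
  history$redo <- history$redo[-length(history$redo)]
  history$undo <- c(history$undo, list(mol))
  if (length(history$undo) > history$capacity) {
    history$undo <- history$undo[-1]
  }
  nxt
}

#' Number of hydrogens the octet rule calls for
#'
#' For a p-block element with V valence electrons and B existing bonds the
#' count is clamp(8 - V - B, 0, 3): enough bonds to complete the octet, but
#' never more than three hydrogens. Non-p-block elements get none.
#'
#' @param symbol Element symbol.
#' @param existing_bonds Number of bonds the atom already has.
#' @return Integer in 0..3.
#' @export
#' @examples
#' hydrogens_needed("C", 1) # 3
#' hydrogens_needed("O", 1) # 1
hydrogens_needed <- function(symbol, existing_bonds = 0) {
  stopifnot(existing_bonds >= 0)
  rec <- lookup_element(symbol)
  if (rec$block != "p") return(0L)
  as.integer(max(0, min(3, 8 - rec$valence_electrons - existing_bonds)))
}

# Unit vectors from atom i toward each of its bonded neighbors.
neighbor_directions <- function(mol, i) {
  nb <- bonded_atoms(mol, i)
  if (length(nb) == 0) return(matrix(numeric(), 0, 3))
  t(vapply(nb, function(j) {
    unit_vector(mol$coords[j, ] - mol$coords[i, ], "bond vector")
  }, numeric(3)))
}

# Deterministic direction that maximizes the minimum angle to the given
# unit vectors: analytically the negative normalized vector sum for 1-3
# existing directions, a golden-spiral grid search otherwise.
open_direction <- function(dirs, default = c(0, 0, 1)) {
  m <- nrow(dirs)
  if (m == 0) return(default)
  if (m <= 3) {
    s <- colSums(dirs)
    if (vnorm(s) > 1e-8) return(-s / vnorm(s))
    # balanced arrangement (e.g. linear or trigonal): fall through to grid
  }
  npts <- 2000
  k <- seq_len(npts)
  phi <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * k - 1) / npts
  r <- sqrt(pmax(0, 1 - z^2))
  th <- 2 * pi * k / phi
  cand <- cbind(r * cos(th), r * sin(th), z)
  minang <- apply(cand %*% t(dirs), 1, max) # max cosine = min angle
  cand[which.min(minang), ]
}

# Place `count` hydrogens on atom `target`, which must have exactly zero or
# one existing bond; directions come from the hybridization's ideal set
# aligned so its first member points along the existing bond.
hydrogen_fill_positions <- function(mol, target, count, hyb) {
  if (count == 0) return(matrix(numeric(), 0, 3))
  ideal <- ideal_directions(hyb$kind)
  dirs <- neighbor_directions(mol, target)
  if (nrow(dirs) == 0) {
    chosen <- ideal[seq_len(min(count, nrow(ideal))), , drop = FALSE]
  } else {
    rot <- alignment_rotation(ideal[1, ], dirs[1, ])
    aligned <- ideal %*% t(rot)
    avail <- aligned[-1, , drop = FALSE]
    chosen <- avail[seq_len(min(count, nrow(avail))), , drop = FALSE]
  }
  len <- covalent_radius(mol$symbols[target]) + covalent_radius("H")
  sweep(chosen * len, 2, mol$coords[target, ], "+")
}

append_atom <- function(mol, symbol, position, bond_to = NULL) {
  mol$symbols <- c(mol$symbols, normalize_symbol(symbol))
  mol$coords <- rbind(mol$coords, matrix(position, 1, 3))
  if (!is.null(bond_to)) {
    mol$bonds <- canonical_bonds(rbind(mol$bonds,
                                       c(bond_to, n_atoms(mol))),
                                 n_atoms(mol))
  }
  mol
}

fill_hydrogens <- function(mol, target, hyb) {
  sym <- mol$symbols[target]
  if (!is_p_block(sym)) return(mol)
  need <- hydrogens_needed(sym, length(bonded_atoms(mol, target)))
  if (need == 0) return(mol)
  pos <- hydrogen_fill_positions(mol, target, need, hyb)
  for (k in seq_len(nrow(pos))) {
    mol <- append_atom(mol, "H", pos[k, ], bond_to = target)
  }
  mol
}

#' Change the element of an atom
#'
#' With two or more bonds only the element type changes and coordinates are
#' untouched. With exactly one bond the atom is repositioned along its bond
#' direction at the new covalent-radii sum from its neighbor, and (for
#' p-block elements) hydrogens are autocompleted per the octet rule at the
#' ideal angles of `hyb`. An isolated atom changes symbol in place.
#'
#' @param mol A [molecule()].
#' @param target Atom index to change.
#' @param new_symbol Element symbol to change to.
#' @param hyb Hybridization used for hydrogen placement (see
#'   [hybridization()]).
#' @param history Optional [edit_history()]; the pre-edit state is pushed.
#' @return The edited molecule.
#' @export
change_element <- function(mol, target, new_symbol, hyb = hybridization("sp3"),
                           history = NULL) {
  target <- check_atom_index(mol, target)
  new_symbol <- normalize_symbol(new_symbol)
  lookup_element(new_symbol)
  record_edit(history, mol)
  nb <- bonded_atoms(mol, target)
  mol$symbols[target] <- new_symbol
  if (length(nb) == 1) {
    dir <- unit_vector(mol$coords[target, ] - mol$coords[nb, ], "bond vector")
    len <- covalent_radius(new_symbol) + covalent_radius(mol$symbols[nb])
    mol$coords[target, ] <- mol$coords[nb, ] + len * dir
    mol <- fill_hydrogens(mol, target, hyb)
  }
  mol
}

#' Add an atom bonded to an existing atom
#'
#' The new atom is placed at the covalent-radii sum from `parent`, in the
#' direction that maximizes the minimum angle to the parent's existing
#' bonds (a fixed default direction when the parent has none). Hydrogens
#' are then autocompleted on the NEW atom per the octet rule, counting its
#' single bond to the parent.
#'
#' @param mol A [molecule()].
#' @param parent Index of the atom to attach to.
#' @param symbol Element of the new atom (default carbon, the default
#'   drawing element).
#' @param hyb Hybridization for hydrogen placement.
#' @param history Optional [edit_history()].
#' @return The edited molecule; the new heavy atom is at index
#'   `n_atoms(mol) + 1` of the input.
#' @export
add_bonded_atom <- function(mol, parent, symbol = "C",
                            hyb = hybridization("sp3"), history = NULL) {
  parent <- check_atom_index(mol, parent)
  symbol <- normalize_symbol(symbol)
  lookup_element(symbol)
  record_edit(history, mol)
  dir <- open_direction(neighbor_directions(mol, parent))
  len <- covalent_radius(mol$symbols[parent]) + covalent_radius(symbol)
  mol <- append_atom(mol, symbol, mol$coords[parent, ] + len * dir,
                     bond_to = parent)
  fill_hydrogens(mol, n_atoms(mol), hyb)
}

#' Add a single hydrogen to an atom
#'
#' One hydrogen is placed at the covalent-radii sum from `target`, in the
#' direction that maximizes the minimum angular separation from the
#' target's existing bonds. No other atom moves, so the result is often not
#' ideal geometry; see [optimize_geometry()].
#'
#' @param mol A [molecule()].
#' @param target Atom index receiving the hydrogen.
#' @param history Optional [edit_history()].
#' @return The edited molecule.
#' @export
add_hydrogen <- function(mol, target, history = NULL) {
  target <- check_atom_index(mol, target)
  record_edit(history, mol)
  dir <- open_direction(neighbor_directions(mol, target))
  len <- covalent_radius(mol$symbols[target]) + covalent_radius("H")
  append_atom(mol, "H", mol$coords[target, ] + len * dir, bond_to = target)
}

#' Delete an atom (and its attached hydrogens)
#'
#' Removes the target atom together with every hydrogen directly bonded to
#' it; all incident bonds disappear and the remaining atoms are re-indexed
#' preserving their order.
#'
#' @param mol A [molecule()].
#' @param target Atom index to delete.
#' @param history Optional [edit_history()].
#' @return The edited molecule.
#' @export
delete_atom <- function(mol, target, history = NULL) {
  target <- check_atom_index(mol, target)
  record_edit(history, mol)
  nb <- bonded_atoms(mol, target)
  drop <- c(target, nb[mol$symbols[nb] == "H"])
  keep <- setdiff(seq_len(n_atoms(mol)), drop)
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[!(b[, 1] %in% drop | b[, 2] %in% drop), , drop = FALSE]
  molecule(mol$symbols[keep], mol$coords[keep, , drop = FALSE],
           bonds = cbind(remap[b[, 1]], remap[b[, 2]]), title = mol$title)
}

#' Add or delete a bond
#'
#' Pure connectivity edits: coordinates never move. Adding an existing bond
#' or deleting a missing one is an error.
#'
#' @param mol A [molecule()].
#' @param i,j Distinct atom indices.
#' @param history Optional [edit_history()].
#' @return The edited molecule.
#' @export
add_bond <- function(mol, i, j, history = NULL) {
  i <- check_atom_index(mol, i); j <- check_atom_index(mol, j)
  if (i == j) mf_stop("cannot bond an atom to itself", "bad_index")
  if (has_bond(mol, i, j)) {
    mf_stop(sprintf("bond %d-%d already exists", min(i, j), max(i, j)),
            "duplicate_bond")
  }
  record_edit(history, mol)
  mol$bonds <- canonical_bonds(rbind(mol$bonds, c(i, j)), n_atoms(mol))
  mol
}

#' @rdname add_bond
#' @export
delete_bond <- function(mol, i, j, history = NULL) {
  b <- require_bond(mol, i, j)
  record_edit(history, mol)
  keep <- !(mol$bonds[, 1] == b[1] & mol$bonds[, 2] == b[2])
  mol$bonds <- mol$bonds[keep, , drop = FALSE]
  mol
}

#' Rotate a fragment about a bond
#'
#' Splits the molecule at a non-ring bond and rotates the smaller of the
#' two fragments (on a tie, the fragment containing `j`, the second index)
#' about the bond axis by `angle` degrees, right-handed about i->j. Ring
#' bonds cannot be rotated about.
#'
#' @param mol A [molecule()].
#' @param i,j Atom indices of an existing non-ring bond.
#' @param angle Rotation in degrees.
#' @param history Optional [edit_history()].
#' @return The edited molecule.
#' @export
rotate_fragment <- function(mol, i, j, angle, history = NULL) {
  i <- check_atom_index(mol, i); j <- check_atom_index(mol, j)
  parts <- split_by_bond(mol, i, j) # raises ring_bond / no_such_bond
  record_edit(history, mol)
  moving <- if (length(parts$side_i) < length(parts$side_j)) parts$side_i
            else parts$side_j
  axis <- mol$coords[j, ] - mol$coords[i, ]
  rotate_molecule(mol, angle, axis = axis, subset = moving,
                  anchor = mol$coords[i, ])
}

#' Apply a plain-text edit script
#'
#' One edit per line, 1-based atom indices, blank lines and `#` comments
#' ignored: `addatom PARENT SYMBOL`, `chelem I SYMBOL`, `delatom I`,
#' `addbond I J`, `delbond I J`, `rotbond I J DEGREES`, `addh I`, `undo`,
#' `redo`.
#'
#' @param mol A [molecule()].
#' @param lines Character vector of script lines (or one multi-line string).
#' @param history An [edit_history()] (created if `NULL` so `undo` works).
#' @param hyb Hybridization for the atom-adding commands.
#' @return The edited molecule.
#' @export
apply_edit_script <- function(mol, lines, history = NULL,
                              hyb = hybridization("sp3")) {
  if (is.null(history)) history <- edit_history()
  lines <- strsplit(paste(lines, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  for (raw in lines) {
    line <- trimws(sub("#.*", "", raw))
    if (!nzchar(line)) next
    f <- strsplit(line, "[ \t]+")[[1]]
    cmd <- tolower(f[1])
    need <- function(k) {
      if (length(f) < k + 1) {
        mf_stop(sprintf("edit command '%s' needs %d argument(s): '%s'",
                        cmd, k, line), "parse_error")
      }
    }
    mol <- switch(cmd,
      addatom = { need(2); add_bonded_atom(mol, as.integer(f[2]), f[3],
                                           hyb, history) },
      chelem  = { need(2); change_element(mol, as.integer(f[2]), f[3],
                                          hyb, history) },
      delatom = { need(1); delete_atom(mol, as.integer(f[2]), history) },
      addbond = { need(2); add_bond(mol, as.integer(f[2]), as.integer(f[3]),
                                    history) },
      delbond = { need(2); delete_bond(mol, as.integer(f[2]),
                                       as.integer(f[3]), history) },
      rotbond = { need(3); rotate_fragment(mol, as.integer(f[2]),
                                           as.integer(f[3]),
                                           as.numeric(f[4]), history) },
      addh    = { need(1); add_hydrogen(mol, as.integer(f[2]), history) },
      undo    = undo(history, mol),
      redo    = redo(history, mol),
      mf_stop(sprintf("unknown edit command: '%s'", cmd), "parse_error")
    )
  }
  mol
}
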