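# The Molecule container: an ordered atom list (element symbol + Cartesian
# coordinates in Angstrom) and an unordered bond set over 1-based atom
# indices. Bonds carry no order attribute.

#' Construct a molecule
#'
#' @param symbols Character vector of element symbols (case-normalized on
#'   construction).
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom). A single atom may be given as a length-3 vector.
#' @param bonds Two-column integer matrix of 1-based atom index pairs (or a
#'   list of length-2 vectors). Order within a pair and duplicate pairs are
#'   canonicalized away.
#' @param title Free-text title (the XYZ comment line).
#' @return An object of class `molecule`.
#' @export
#' @examples
#' m <- molecule("H", c(0, 0, 0))
#' n_atoms(m)
molecule <- function(symbols = character(), coords = matrix(numeric(), 0, 3),
                     bonds = NULL, title = "") {
  symbols <- if (length(symbols)) normalize_symbol(symbols) else character()
  if (is.null(dim(coords))) {
    coords <- matrix(as.numeric(coords), ncol = 3, byrow = TRUE)
  }
  coords <- unname(as.matrix(coords))
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3 && length(symbols) > 0) {
    mf_stop("coordinates must have three columns (x, y, z)", "parse_error")
  }
  if (nrow(coords) != length(symbols)) {
    mf_stop(sprintf("%d symbols but %d coordinate rows", length(symbols),
                    nrow(coords)), "malformed_count")
  }
  m <- structure(
    list(symbols = symbols, coords = coords,
         bonds = canonical_bonds(bonds, length(symbols)),
         title = as.character(title)[1]),
    class = "molecule"
  )
  m
}

canonical_bonds <- function(bonds, n) {
  if (is.null(bonds) || (is.matrix(bonds) && nrow(bonds) == 0) ||
      length(bonds) == 0) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  if (is.list(bonds)) bonds <- do.call(rbind, bonds)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(is.na(bonds)) || any(bonds < 1) || any(bonds > n)) {
    mf_stop("bond references a nonexistent atom index", "bad_index")
  }
  if (any(bonds[, 1] == bonds[, 2])) {
    mf_stop("bond joins an atom to itself", "bad_index")
  }
  b <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  b <- unique(b)
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]
  dimnames(b) <- list(NULL, c("i", "j"))
  b
}

#' Number of atoms in a molecule
#' @param mol A [molecule()].
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$symbols)

#' Number of bonds in a molecule
#' @param mol A [molecule()].
#' @return Integer bond count.
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

check_atom_index <- function(mol, i, what = "atom index") {
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 1) || any(i > n_atoms(mol))) {
    mf_stop(sprintf("%s out of range: %s (molecule has %d atoms)", what,
                    paste(i, collapse = ", "), n_atoms(mol)), "bad_index")
  }
  i
}

#' Test whether a bond exists
#' @param mol A [molecule()].
#' @param i,j Atom indices (1-based).
#' @return `TRUE` if the unordered pair \{i, j\} is bonded.
#' @export
has_bond <- function(mol, i, j) {
  i <- check_atom_index(mol, i)
  j <- check_atom_index(mol, j)
  lo <- min(i, j); hi <- max(i, j)
  any(mol$bonds[, 1] == lo & mol$bonds[, 2] == hi)
}

#' Indices of atoms bonded to an atom
#' @param mol A [molecule()].
#' @param i Atom index.
#' @return Integer vector of neighbor indices (sorted).
#' @export
bonded_atoms <- function(mol, i) {
  i <- check_atom_index(mol, i)
  b <- mol$bonds
  sort(unname(c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])))
}

#' Molecular formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (all elements alphabetical when no carbon is present).
#'
#' @param mol A [molecule()].
#' @return Single formula string, e.g. `"CH4"`.
#' @export
molecular_formula <- function(mol) {
  if (n_atoms(mol) == 0) return("")
  counts <- table(mol$symbols)
  syms <- sort(names(counts))
  if ("C" %in% syms) {
    syms <- c("C", intersect("H", syms), setdiff(syms, c("C", "H")))
  }
  paste0(vapply(syms, function(s) {
    k <- counts[[s]]
    if (k == 1) s else paste0(s, k)
  }, character(1)), collapse = "")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds\n",
              if (nzchar(molecular_formula(x))) molecular_formula(x) else "(empty)",
              n_atoms(x), n_bonds(x)))
  if (nzchar(x$title)) cat("  title:", x$title, "\n")
  invisible(x)
}

#' @export
format.molecule <- function(x, ...) {
  sprintf("<molecule %s: %d atoms, %d bonds>", molecular_formula(x),
          n_atoms(x), n_bonds(x))
}

# Internal sanity check used by property tests and after edits.
validate_molecule <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  n <- n_atoms(mol)
  stopifnot(nrow(mol$coords) == n, !any(is.na(mol$coords)))
  b <- mol$bonds
  if (nrow(b) > 0) {
    stopifnot(all(b >= 1), all(b <= n), all(b[, 1] < b[, 2]),
              !anyDuplicated(b))
  }
  invisible(mol)
}
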