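# XYZ read/write and a preliminary MDL MOL V2000 reader.
#
# XYZ parsing is deliberately forgiving: any run of blanks or tabs separates
# fields, CRLF line endings and trailing blank lines are accepted, and
# column alignment is irrelevant. XYZ carries no connectivity, so the bond
# set of a freshly read molecule is empty; see perceive_bonds().

split_text_lines <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) mf_stop("either 'file' or 'text' required", "parse_error")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  sub("\r$", "", lines)
}

#' Read an XYZ coordinate file
#'
#' Parses the OpenBabel XYZ dialect: an atom count line, a free-text
#' comment line, then one `symbol x y z` line per atom. Whitespace is
#' flexible; the declared atom count is validated against the body. The
#' returned molecule has an empty bond set (the format stores no
#' connectivity) — run [perceive_bonds()] afterwards, as [load_molecule()]
#' does.
#'
#' @param file Path to an `.xyz` file. Ignored when `text` is given.
#' @param text Optional character scalar (or vector of lines) holding the
#'   file content directly.
#' @return A [molecule()] with zero bonds; the comment line becomes `title`.
#' @export
#' @examples
#' read_xyz(text = "1\nlone hydrogen\nH 0 0 0\n")
read_xyz <- function(file = NULL, text = NULL) {
  lines <- split_text_lines(file, text)
  if (length(lines) < 1 || !nzchar(trimws(lines[1]))) {
    mf_stop("empty XYZ input", "parse_error")
  }
  count <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(count) || count < 0) {
    mf_stop(sprintf("first XYZ line is not an atom count: '%s'", lines[1]),
            "parse_error")
  }
  title <- if (length(lines) >= 2) lines[2] else ""
  body <- lines[-(1:min(2, length(lines)))]
  while (length(body) > 0 && !nzchar(trimws(body[length(body)]))) {
    body <- body[-length(body)]
  }
  if (length(body) != count) {
    mf_stop(sprintf("XYZ header declares %d atoms but body has %d atom lines",
                    count, length(body)), "malformed_count")
  }
  symbols <- character(count)
  coords <- matrix(NA_real_, count, 3)
  for (k in seq_len(count)) {
    fields <- strsplit(trimws(body[k]), "[ \t]+")[[1]]
    if (length(fields) < 4) {
      mf_stop(sprintf("cannot parse XYZ atom line %d: '%s'", k + 2, body[k]),
              "parse_error")
    }
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(xyz))) {
      mf_stop(sprintf("non-numeric coordinates on XYZ line %d: '%s'", k + 2,
                      body[k]), "parse_error")
    }
    symbols[k] <- fields[1]
    coords[k, ] <- xyz
  }
  symbols <- normalize_symbol(symbols)
  covalent_radius(symbols) # raise unknown-element before constructing
  molecule(symbols, coords, title = title)
}

#' Write a molecule to XYZ format
#'
#' Emits canonical XYZ: atom count, title line, then `symbol x y z` with
#' six decimal places. Connectivity is not representable in XYZ and is
#' dropped.
#'
#' @param mol A [molecule()].
#' @param file Optional path; when `NULL` the text is returned only.
#' @return The XYZ text, invisibly when written to `file`.
#' @export
write_xyz <- function(mol, file = NULL) {
  validate_molecule(mol)
  lines <- c(
    as.character(n_atoms(mol)),
    mol$title,
    sprintf("%s %.6f %.6f %.6f", mol$symbols,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  )
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}

#' Read an MDL MOL (V2000) connection table
#'
#' Preliminary reader covering the counts line, atom block and bond block
#' only; property blocks and all per-atom fields beyond coordinates and the
#' symbol are ignored. Bond order digits are read but discarded: the
#' molecule model stores plain connectivity without orders.
#'
#' @param file Path to a `.mol` file. Ignored when `text` is given.
#' @param text Optional character scalar holding the file content.
#' @return A [molecule()] with bonds taken from the bond block.
#' @export
read_mol <- function(file = NULL, text = NULL) {
  lines <- split_text_lines(file, text)
  if (length(lines) < 4) {
    mf_stop("MOL input shorter than header + counts line", "parse_error")
  }
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 0 || nbonds < 0) {
    mf_stop(sprintf("malformed MOL counts line: '%s'", counts),
            "malformed_count")
  }
  if (length(lines) < 4 + natoms + nbonds) {
    mf_stop(sprintf("MOL body truncated: expected %d atom + %d bond lines",
                    natoms, nbonds), "malformed_count")
  }
  symbols <- character(natoms)
  coords <- matrix(NA_real_, natoms, 3)
  for (k in seq_len(natoms)) {
    ln <- lines[4 + k]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 1, 10),
                                         substr(ln, 11, 20),
                                         substr(ln, 21, 30))))
    sym <- trimws(substr(ln, 31, 34))
    if (any(is.na(xyz)) || !nzchar(sym)) {
      # fall back to whitespace parsing for hand-written tables
      fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(fields) < 4) {
        mf_stop(sprintf("cannot parse MOL atom line %d: '%s'", 4 + k, ln),
                "parse_error")
      }
      xyz <- suppressWarnings(as.numeric(fields[1:3]))
      sym <- fields[4]
      if (any(is.na(xyz))) {
        mf_stop(sprintf("cannot parse MOL atom line %d: '%s'", 4 + k, ln),
                "parse_error")
      }
    }
    symbols[k] <- sym
    coords[k, ] <- xyz
  }
  bonds <- matrix(integer(), 0, 2)
  if (nbonds > 0) {
    bonds <- matrix(NA_integer_, nbonds, 2)
    for (k in seq_len(nbonds)) {
      ln <- lines[4 + natoms + k]
      ij <- suppressWarnings(as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6))))
      if (any(is.na(ij))) {
        fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
        ij <- suppressWarnings(as.integer(fields[1:2]))
      }
      if (any(is.na(ij))) {
        mf_stop(sprintf("cannot parse MOL bond line %d: '%s'",
                        4 + natoms + k, ln), "parse_error")
      }
      if (any(ij < 1) || any(ij > natoms)) {
        mf_stop(sprintf("MOL bond line %d references atom %d of %d",
                        4 + natoms + k, max(ij), natoms), "bad_index")
      }
      bonds[k, ] <- ij
    }
  }
  symbols <- normalize_symbol(symbols)
  covalent_radius(symbols)
  molecule(symbols, coords, bonds = bonds, title = trimws(lines[1]))
}

#' Load a molecule from a file, dispatching on extension
#'
#' `.xyz` files are read with [read_xyz()] and bonds are then perceived
#' from geometry; `.mol` files are read with [read_mol()] and keep their
#' explicit bond block (pass `perceive = TRUE` to re-perceive anyway).
#' Other extensions are rejected with a warning, mirroring interactive
#' loaders that ignore files of the wrong type.
#'
#' @param path File path ending in `.xyz` or `.mol` (case-insensitive).
#' @param perceive Force bond perception regardless of format.
#' @param factor Bond-perception distance factor, see [perceive_bonds()].
#' @return A [molecule()].
#' @export
load_molecule <- function(path, perceive = NA, factor = 1.2) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("xyz", "mol")) {
    mf_warn(sprintf("file '%s' ignored: extension '.%s' is not .xyz or .mol",
                    path, ext), "extension_rejected")
    mf_stop(sprintf("unsupported file extension: '.%s'", ext),
            "extension_rejected")
  }
  if (!file.exists(path)) {
    mf_stop(sprintf("file not found: '%s'", path), "file_not_found")
  }
  if (ext == "xyz") {
    mol <- read_xyz(file = path)
    if (is.na(perceive) || isTRUE(perceive)) {
      mol <- perceive_bonds(mol, factor = factor)
    }
  } else {
    mol <- read_mol(file = path)
    if (isTRUE(perceive)) mol <- perceive_bonds(mol, factor = factor)
  }
  mol
}
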