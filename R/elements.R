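# Element property table: covalent radii, Jmol display colors, main-group
# valence electron counts and atomic masses, shipped as a plain TSV under
# inst/extdata so it is inspectable and replaceable.

.molforge <- new.env(parent = emptyenv())

#' Element property table
#'
#' Returns the per-element constant table used throughout the package:
#' covalent radius (Angstrom, Cordero 2008 compilation, the same values
#' shipped with RDKit and Open Babel), display color (Jmol scheme), number
#' of valence electrons (s + p, main-group elements only; `NA` for d- and
#' f-block), atomic mass (u) and periodic block.
#'
#' The table is read once per session from the file shipped with the
#' package, or from `getOption("molforge.elements")` if that option names an
#' alternative TSV with the same columns.
#'
#' @param path Optional path to an alternative element TSV.
#' @return A data frame with columns `symbol`, `z`, `covalent_radius`,
#'   `mass`, `valence_electrons`, `block`, `red`, `green`, `blue`.
#' @export
#' @examples
#' head(element_table())
element_table <- function(path = NULL) {
  if (!is.null(path)) {
    return(read_element_table(path))
  }
  opt <- getOption("molforge.elements")
  if (!is.null(opt)) {
    return(read_element_table(opt))
  }
  if (is.null(.molforge$elements)) {
    shipped <- system.file("extdata", "elements.tsv", package = "molforge",
                           mustWork = TRUE)
    .molforge$elements <- read_element_table(shipped)
  }
  .molforge$elements
}

read_element_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("symbol", "covalent_radius", "mass", "valence_electrons",
              "block", "red", "green", "blue")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    mf_stop(sprintf("element table '%s' lacks columns: %s", path,
                    paste(missing, collapse = ", ")), "parse_error")
  }
  stopifnot(all(tab$covalent_radius > 0), all(tab$mass > 0))
  rownames(tab) <- tab$symbol
  tab
}

#' Normalize an element symbol
#'
#' Case-normalizes symbols so that `"CL"`, `"cl"` and `"Cl"` all refer to
#' chlorine.
#'
#' @param symbol Character vector of element symbols.
#' @return Character vector of canonical symbols.
#' @export
normalize_symbol <- function(symbol) {
  s <- trimws(as.character(symbol))
  paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
}

#' Look up an element record
#'
#' @param symbol Single element symbol; matching is case-insensitive.
#' @return A one-row data frame (see [element_table()]) for the element.
#' @export
#' @examples
#' lookup_element("cl")$symbol # "Cl"
lookup_element <- function(symbol) {
  tab <- element_table()
  s <- normalize_symbol(symbol)
  if (length(s) != 1 || is.na(s) || !s %in% tab$symbol) {
    mf_stop(sprintf("unknown element symbol: '%s'", symbol), "unknown_element")
  }
  tab[s, , drop = FALSE]
}

# Vectorized property accessors; all case-normalize and raise
# molforge_unknown_element on a miss.
element_property <- function(symbol, column) {
  tab <- element_table()
  s <- normalize_symbol(symbol)
  bad <- !s %in% tab$symbol
  if (any(bad)) {
    mf_stop(sprintf("unknown element symbol: '%s'",
                    paste(unique(symbol[bad]), collapse = "', '")),
            "unknown_element")
  }
  tab[s, column]
}

#' Covalent radius of one or more elements
#'
#' @param symbol Character vector of element symbols.
#' @return Numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(symbol) element_property(symbol, "covalent_radius")

#' Atomic mass of one or more elements
#'
#' @param symbol Character vector of element symbols.
#' @return Numeric vector of atomic masses in u.
#' @export
atomic_mass <- function(symbol) element_property(symbol, "mass")

#' Display color of one or more elements
#'
#' Jmol/CPK color scheme, as hex strings usable directly in SVG output.
#'
#' @param symbol Character vector of element symbols.
#' @return Character vector of `#RRGGBB` hex colors.
#' @export
element_color <- function(symbol) {
  tab <- element_table()
  s <- normalize_symbol(symbol)
  element_property(symbol, "red") # index check
  sprintf("#%02X%02X%02X", tab[s, "red"], tab[s, "green"], tab[s, "blue"])
}

#' Is an element in the p block?
#'
#' Hydrogen autocompletion and octet-rule counting apply to p-block
#' elements only; hydrogen itself is s-block and handled by its own rule.
#'
#' @param symbol Character vector of element symbols.
#' @return Logical vector.
#' @export
#' @examples
#' is_p_block(c("N", "Fe", "C")) # TRUE FALSE TRUE
is_p_block <- function(symbol) {
  element_property(symbol, "block") == "p"
}

#' Main-group valence electron count
#'
#' @param symbol Character vector of element symbols.
#' @return Integer vector; `NA` for d-/f-block elements.
#' @export
valence_electrons <- function(symbol) {
  element_property(symbol, "valence_electrons")
}

# Classed conditions: every error the package raises carries class
# "molforge_<what>" plus "molforge_error" so callers can dispatch.
mf_stop <- function(msg, class) {
  stop(structure(
    class = c(paste0("molforge_", class), "molforge_error", "error",
              "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

mf_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("molforge_", class), "molforge_warning", "warning",
              "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
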