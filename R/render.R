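# Ball-and-stick rendering to SVG with painter's-algorithm depth sorting.
#
# Orthographic projection: molecular x/y map to the canvas (y flipped so
# +y points up), z is depth with the viewer on the +z side, so atoms are
# drawn in ascending-z order (backmost first). Each atom contributes its
# shaded sphere followed by one line per bond it "owns": the bonds to
# neighbors drawn after it. A bond line starts at the 3D intersection of
# the bond with the back atom's sphere surface and ends at the front
# atom's projected center. Spheres are assumed not to overlap; there is no
# occlusion clipping beyond the painter's order.

#' Scene parameters for SVG rendering
#'
#' @param width,height Canvas size in pixels.
#' @param scale Pixels per Angstrom.
#' @param sphere_scale Multiplier on the covalent radius giving the drawn
#'   sphere radius (default 0.5, a conventional ball-and-stick shrink).
#' @param gradient_cutoff Radial-gradient shading is used only when the
#'   molecule has at most this many atoms (default 250) — gradients are
#'   expensive, so larger molecules get flat fills.
#' @param label_atoms Draw element-symbol labels at atom centers.
#' @param highlight Atom indices to mark with a light-yellow halo.
#' @return An object of class `scene`.
#' @export
scene <- function(width = 600, height = 600, scale = 40, sphere_scale = 0.5,
                  gradient_cutoff = 250, label_atoms = FALSE,
                  highlight = integer()) {
  stopifnot(width > 0, height > 0, scale > 0, sphere_scale > 0,
            gradient_cutoff > 0)
  structure(list(width = width, height = height, scale = scale,
                 sphere_scale = sphere_scale,
                 gradient_cutoff = gradient_cutoff,
                 label_atoms = isTRUE(label_atoms),
                 highlight = as.integer(highlight)),
            class = "scene")
}

#' Painter's-algorithm depth order
#'
#' Atom indices sorted by ascending z (backmost first, viewer on the +z
#' side); ties keep the original atom order.
#'
#' @param mol A [molecule()].
#' @return Integer permutation of `1:n_atoms(mol)`.
#' @export
depth_sort <- function(mol) {
  order(mol$coords[, 3]) # base::order is stable
}

# Simple shade helpers for the radial gradient stops.
mix_hex <- function(hex, other, w) {
  a <- grDevices::col2rgb(hex)[, 1]
  b <- grDevices::col2rgb(other)[, 1]
  m <- round((1 - w) * a + w * b)
  sprintf("#%02X%02X%02X", m[1], m[2], m[3])
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt <- function(x) formatC(x, format = "f", digits = 2)

#' Render a molecule to an SVG ball-and-stick drawing
#'
#' Atoms are drawn back-to-front (see [depth_sort()]): for each atom a
#' filled circle (radius `sphere_scale` times its covalent radius, Jmol
#' element color, radial-gradient shading unless the molecule exceeds
#' `gradient_cutoff` atoms), then one line per bond to each connected atom
#' drawn later, starting at the back atom's sphere surface and ending at
#' the front atom's center. Highlighted atoms get a light-yellow halo
#' behind their sphere; labels are drawn on top when requested. Circles
#' carry `data-atom` and `data-z` attributes so the paint order is
#' machine-checkable.
#'
#' @param mol A non-empty [molecule()].
#' @param sc A [scene()].
#' @param file Optional path to write the SVG document to.
#' @return The SVG document as a single string, invisibly when written to
#'   `file`.
#' @export
#' @examples
#' svg <- render_svg(make_fixture("methane"), scene(scale = 60))
render_svg <- function(mol, sc = scene(), file = NULL) {
  if (n_atoms(mol) == 0) {
    mf_stop("cannot render an empty molecule", "empty_molecule")
  }
  validate_molecule(mol)
  n <- n_atoms(mol)
  use_gradients <- n <= sc$gradient_cutoff
  center <- colMeans(mol$coords)
  px <- sc$width / 2 + sc$scale * (mol$coords[, 1] - center[1])
  py <- sc$height / 2 - sc$scale * (mol$coords[, 2] - center[2])
  r_draw <- sc$sphere_scale * covalent_radius(mol$symbols) # Angstrom
  fill_color <- element_color(mol$symbols)

  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d" viewBox="0 0 %d %d">'),
                   round(sc$width), round(sc$height),
                   round(sc$width), round(sc$height)))
  if (use_gradients) {
    syms <- unique(mol$symbols)
    defs <- vapply(syms, function(s) {
      base <- element_color(s)
      paste0('<radialGradient id="grad-', s, '" cx="0.35" cy="0.35" r="0.8">',
             '<stop offset="0%" stop-color="', mix_hex(base, "#FFFFFF", 0.6),
             '"/><stop offset="55%" stop-color="', base,
             '"/><stop offset="100%" stop-color="', mix_hex(base, "#000000", 0.4),
             '"/></radialGradient>')
    }, character(1))
    out <- c(out, "<defs>", defs, "</defs>")
  }

  ord <- depth_sort(mol)
  paint_pos <- integer(n)
  paint_pos[ord] <- seq_len(n)
  for (a in ord) {
    rp <- sc$scale * r_draw[a]
    if (a %in% sc$highlight) {
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="#FFFF99" class="halo"/>',
        fmt(px[a]), fmt(py[a]), fmt(rp * 1.35)))
    }
    fill <- if (use_gradients) paste0("url(#grad-", mol$symbols[a], ")")
            else fill_color[a]
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" data-atom="%d" data-z="%s"/>',
      fmt(px[a]), fmt(py[a]), fmt(rp), fill, a,
      formatC(mol$coords[a, 3], format = "f", digits = 6)))
    for (nb in bonded_atoms(mol, a)) {
      if (paint_pos[nb] <= paint_pos[a]) next # neighbor already drawn: owns it
      v <- mol$coords[nb, ] - mol$coords[a, ]
      len <- vnorm(v)
      start3 <- if (len > 1e-9) mol$coords[a, ] + (r_draw[a] / len) * v
                else mol$coords[a, ]
      sx <- sc$width / 2 + sc$scale * (start3[1] - center[1])
      sy <- sc$height / 2 - sc$scale * (start3[2] - center[2])
      out <- c(out, sprintf(
        paste0('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#4D4D4D" ',
               'stroke-width="%s" data-bond="%d-%d"/>'),
        fmt(sx), fmt(sy), fmt(px[nb]), fmt(py[nb]),
        fmt(max(1.5, sc$scale * 0.08)), min(a, nb), max(a, nb)))
    }
    if (sc$label_atoms) {
      out <- c(out, sprintf(
        paste0('<text x="%s" y="%s" text-anchor="middle" ',
               'dominant-baseline="middle" font-size="%s" ',
               'font-family="sans-serif">%s</text>'),
        fmt(px[a]), fmt(py[a]), fmt(max(8, rp * 0.9)),
        svg_escape(mol$symbols[a])))
    }
  }
  out <- c(out, "</svg>")
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(doc, file, sep = "")
    return(invisible(doc))
  }
  doc
}
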