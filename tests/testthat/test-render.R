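# SVG output is inspected through xml2; circles carry data-atom/data-z
# attributes precisely so these checks need no pixel rasterization.

test_that("depth sort orders atoms back to front, stably", {
  m <- molecule(c("C", "C", "C"),
                rbind(c(0, 0, 3), c(0, 0, 1), c(0, 0, 2)))
  expect_equal(depth_sort(m), c(2L, 3L, 1L))
  tie <- molecule(c("C", "C"), rbind(c(0, 0, 1), c(1, 0, 1)))
  expect_equal(depth_sort(tie), c(1L, 2L))
  flipped <- m
  flipped$coords[, 3] <- -flipped$coords[, 3]
  expect_equal(depth_sort(flipped), rev(depth_sort(m)))
})

test_that("a single atom renders as one shaded circle and no lines", {
  svg <- render_svg(molecule("C", c(0, 0, 0)), scene())
  expect_length(svg_circles(svg), 1)
  expect_length(svg_lines(svg), 0)
  expect_true(svg_has_gradients(svg))
})

test_that("bond lines start on the back atom's sphere surface", {
  sc <- scene(width = 400, height = 400, scale = 100, sphere_scale = 0.5)
  # diatomic along x: start displaced from the back atom center by its
  # drawn sphere radius, end at the front atom's projected center
  m <- molecule(c("C", "C"), rbind(c(-0.75, 0, 0), c(0.75, 0, 1)),
                bonds = rbind(c(1, 2)))
  svg <- render_svg(m, sc)
  line <- svg_lines(svg)[[1]]
  x1 <- as.numeric(xml2::xml_attr(line, "x1"))
  x2 <- as.numeric(xml2::xml_attr(line, "x2"))
  circ <- svg_circles(svg)
  backs <- as.integer(xml2::xml_attr(circ, "data-atom"))
  cx <- as.numeric(xml2::xml_attr(circ, "cx"))
  back_cx <- cx[backs == 1]
  front_cx <- cx[backs == 2]
  r3d <- 0.5 * covalent_radius("C")
  dir <- (m$coords[2, ] - m$coords[1, ])
  step_x <- r3d * dir[1] / sqrt(sum(dir^2)) * sc$scale
  expect_equal(x1, back_cx + step_x, tolerance = 0.02)
  expect_equal(x2, front_cx, tolerance = 0.02)

  # bond exactly along the view axis: zero projected offset, no error
  axial <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                    bonds = rbind(c(1, 2)))
  svg2 <- render_svg(axial, scene())
  line2 <- svg_lines(svg2)[[1]]
  expect_equal(as.numeric(xml2::xml_attr(line2, "x1")),
               as.numeric(xml2::xml_attr(line2, "x2")), tolerance = 0.02)
})

test_that("painter's order holds and every bond owns one line", {
  for (name in c("methane", "ethane_staggered", "benzene", "s_2_butanol")) {
    m <- make_fixture(name)
    svg <- render_svg(m, scene())
    z <- as.numeric(xml2::xml_attr(svg_circles(svg), "data-z"))
    expect_true(all(diff(z) >= 0)) # circles appear in ascending depth
    expect_length(svg_lines(svg), n_bonds(m))
    bonds_drawn <- sort(xml2::xml_attr(svg_lines(svg), "data-bond"))
    expect_equal(bonds_drawn,
                 sort(sprintf("%d-%d", m$bonds[, 1], m$bonds[, 2])))
  }
})

test_that("the gradient cutoff switches large molecules to flat fills", {
  grid_cluster <- function(n) {
    side <- ceiling(n^(1 / 3))
    pts <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                 z = seq_len(side))) * 10
    molecule(rep("C", n), pts[seq_len(n), ])
  }
  expect_true(svg_has_gradients(render_svg(grid_cluster(250), scene())))
  expect_false(svg_has_gradients(render_svg(grid_cluster(251), scene())))
})

test_that("fills use element colors, labels and highlights render", {
  m <- make_fixture("methane")
  flat <- render_svg(m, scene(gradient_cutoff = 1)) # force flat fills
  fills <- xml2::xml_attr(svg_circles(flat), "fill")
  atoms <- as.integer(xml2::xml_attr(svg_circles(flat), "data-atom"))
  expect_equal(fills[atoms == 1], element_color("C"))
  expect_equal(fills[atoms == 2], element_color("H"))

  shaded <- render_svg(m, scene())
  expect_true(all(grepl("^url\\(#grad-", xml2::xml_attr(svg_circles(shaded),
                                                        "fill"))))

  lab <- render_svg(m, scene(label_atoms = TRUE))
  texts <- xml2::xml_find_all(xml2::read_xml(lab),
                              ".//*[local-name()='text']")
  expect_length(texts, 5)
  expect_setequal(unique(xml2::xml_text(texts)), c("C", "H"))

  hi <- render_svg(m, scene(highlight = 1))
  halos <- xml2::xml_find_all(xml2::read_xml(hi),
                              ".//*[local-name()='circle'][@class='halo']")
  expect_length(halos, 1)
  expect_equal(xml2::xml_attr(halos, "fill"), "#FFFF99")
})

test_that("rendering an empty molecule is an error", {
  expect_error(render_svg(molecule(), scene()),
               class = "molforge_empty_molecule")
})
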