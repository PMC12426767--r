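# Mesh generators, tagging, measures and file round trips.

test_that("crossed unit-square triangulation has the expected structure", {
  m1 <- build_unit_square_mesh(1)
  expect_equal(nrow(m1$cells), 4L)
  expect_equal(nrow(m1$vertices), 5L)

  m8 <- build_unit_square_mesh(8)
  expect_equal(nrow(m8$cells), 4L * 8^2)
  expect_equal(nrow(m8$boundary_facets), 32L)
  expect_equal(unname(as.vector(table(m8$facet_tags))), rep(8L, 4))

  # every boundary facet tagged exactly once; sides have unit length
  expect_equal(length(m8$facet_tags), nrow(m8$boundary_facets))
  for (s in c("left", "right", "bottom", "top")) {
    expect_equal(region_area(m8, s), 1.0, tolerance = 1e-14)
  }
  expect_equal(sum(sapply(1:4, region_area, mesh = m8)), 4.0,
               tolerance = 1e-14)
  # crossed pattern is symmetric about the vertical axis
  mirrored <- cbind(1 - m8$vertices[, 1], m8$vertices[, 2])
  keys <- paste(round(m8$vertices[, 1], 12), round(m8$vertices[, 2], 12))
  expect_true(all(paste(round(mirrored[, 1], 12),
                        round(mirrored[, 2], 12)) %in% keys))
  expect_error(build_unit_square_mesh(0), "positive")
})

test_that("cylinder mesh approximates areas and respects containment", {
  R <- 1e-3; L <- 2e-3
  cyl <- build_cylinder_mesh(R, L, 2.5e-4)
  wall <- region_area(cyl, "wall")
  expect_lt(wall, 2 * pi * R * L)                # inscribed polyhedron
  expect_gt(wall, 0.98 * 2 * pi * R * L)
  inlet <- region_area(cyl, "inlet")
  expect_lt(inlet, pi * R^2)
  expect_gt(inlet, 0.97 * pi * R^2)
  expect_true(all(cyl$cell_h > 0))
  rad <- sqrt(rowSums(cyl$vertices[, 1:2]^2))
  expect_lte(max(rad), R * (1 + 1e-12))
  # refinement brings the lateral area closer to the closed form
  finer <- build_cylinder_mesh(R, L, 1.25e-4)
  expect_lt(2 * pi * R * L - region_area(finer, "wall"),
            2 * pi * R * L - wall)
  expect_error(build_cylinder_mesh(R, L, 2e-3), "smaller than radius")
})

test_that("boundary-layer stack follows the geometric progression", {
  bl <- boundary_layer_spec()
  e <- 2.5e-4
  hts <- wssbench:::bl_heights(bl, e)
  expect_equal(sum(hts), 0.1 * e * (1.1^0 + 1.1^1 + 1.1^2 + 1.1^3))
  expect_equal(sum(hts) / e, 0.4641, tolerance = 1e-12)

  cyl <- build_cylinder_mesh(1e-3, 2e-3, e, bl)
  # radial gaps next to the wall reproduce the layer heights
  rad <- sort(unique(round(sqrt(rowSums(cyl$vertices[, 1:2]^2)), 12)),
              decreasing = TRUE)
  gaps <- -diff(rad[1:5])
  expect_equal(gaps, hts, tolerance = 1e-9)
  expect_error(boundary_layer_spec(first_layer_fraction = 1.2), "0, 1")
  expect_error(boundary_layer_spec(growth_ratio = 0.9), ">= 1")
  expect_error(boundary_layer_spec(n_layers = 0), ">= 1")
})

test_that("mesh refinement decreases the maximal circumdiameter", {
  hs <- sapply(c(4, 8, 16), function(n) max(build_unit_square_mesh(n)$cell_h))
  expect_true(all(diff(hs) < 0))
  hc <- sapply(c(1e-3 / 2.5, 1e-3 / 4, 1e-3 / 6),
               function(e) max(build_cylinder_mesh(1e-3, 2e-3, e)$cell_h))
  expect_true(all(diff(hc) < 0))
})

test_that("region_area resolves labels and rejects unknown tags", {
  m <- build_unit_square_mesh(4)
  expect_equal(region_area(m, "top"), region_area(m, 4))
  expect_error(region_area(m, "dome"), "available")
  expect_error(region_area(m, 99L), "available")
})

test_that("mesh files round-trip through XDMF and MSH 4.1 with tags", {
  m <- build_unit_square_mesh(8)
  td <- withr::local_tempdir()
  for (fn in c("sq.xdmf", "sq.msh")) {
    p <- file.path(td, fn)
    write_tagged_mesh(m, p)
    m2 <- read_tagged_mesh(p)
    expect_equal(nrow(m2$vertices), nrow(m$vertices))
    expect_equal(nrow(m2$cells), nrow(m$cells))
    expect_equal(nrow(m2$boundary_facets), nrow(m$boundary_facets))
    expect_equal(sort(as.vector(table(m2$facet_tags))),
                 sort(as.vector(table(m$facet_tags))))
    expect_equal(unname(sort(m2$region_names)), unname(sort(m$region_names)))
    expect_equal(region_area(m2, "top"), 1.0, tolerance = 1e-12)
  }
  cyl <- build_cylinder_mesh(1e-3, 2e-3, 4e-4)
  p <- file.path(td, "cyl.msh")
  write_tagged_mesh(cyl, p)
  c2 <- read_tagged_mesh(p, region_map = c("1" = "inlet", "2" = "outlet",
                                           "3" = "wall"))
  expect_equal(region_area(c2, "wall"), region_area(cyl, "wall"),
               tolerance = 1e-12)
})

test_that("meshes without facet data raise an untagged-boundary error", {
  td <- withr::local_tempdir()
  m <- build_unit_square_mesh(2)
  p <- file.path(td, "bare.xdmf")
  write_tagged_mesh(m, p)
  # strip the facet grid
  doc <- xml2::read_xml(p)
  xml2::xml_remove(xml2::xml_find_all(doc, ".//Grid[@Name='facet_tags']"))
  xml2::write_xml(doc, p)
  expect_error(read_tagged_mesh(p), "untagged boundary")
  expect_error(read_tagged_mesh(file.path(td, "nope.msh")), "not found")
})

test_that("split_region carves a tagged subregion and keeps the partition", {
  cyl <- build_cylinder_mesh(1e-3, 2e-3, 4e-4)
  m2 <- split_region(cyl, "wall", function(cen) cen[, 3] > 1e-3, "dome")
  expect_true("dome" %in% m2$region_names)
  expect_equal(region_area(m2, "wall") + region_area(m2, "dome"),
               region_area(cyl, "wall"), tolerance = 1e-15)
})
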