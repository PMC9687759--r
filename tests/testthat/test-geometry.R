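# Antenna parameterization, synthetic tumors, surface-mesh I/O, meshing.

test_that("slot array geometry and feasibility checks", {
  a <- build_antenna(slot_count = 10, slot_width = 0.6e-3, slot_spacing = 0.8e-3)
  expect_equal(a$slotted_span, 10 * 0.6e-3 + 9 * 0.8e-3)   # 13.2 mm
  expect_equal(nrow(a$slot_z), 10)
  expect_equal(unname(a$slot_z[1, ]), c(a$tip_offset, a$tip_offset + 0.6e-3))
  single <- build_antenna(slot_count = 1)
  expect_equal(single$slotted_span, 0.6e-3)
  expect_error(build_antenna(slot_count = 0), "integer >= 1")
  expect_error(build_antenna(slot_count = 10, insertion_depth = 0.01),
               "infeasible")
  expect_error(build_antenna(inner_conductor_radius = 6e-4), "increasing")
})

test_that("ellipsoid tumors carry the closed-form volume", {
  tum <- make_ellipsoid_tumor(c(0.82, 0.855, 1.905) * 1e-2)
  expect_equal(tum$volume, 4 / 3 * pi * prod(c(0.82, 0.855, 1.905) * 1e-2),
               tolerance = 1e-12)
  expect_equal(tum$volume * 1e6, 5.5945, tolerance = 1e-4)
  sph <- make_ellipsoid_tumor(rep(0.01, 3))
  expect_equal(sph$volume, 4.18879e-6, tolerance = 1e-5)
  expect_error(make_ellipsoid_tumor(c(0.01, 0, 0.01)), "positive")
})

test_that("icosphere-based surfaces are closed with near-analytic volume", {
  s <- ellipsoid_surface(c(0.01, 0.012, 0.02), center = c(0, 0, 0.01), subdiv = 3)
  expect_lt(abs(s$volume / (4 / 3 * pi * 0.01 * 0.012 * 0.02) - 1), 0.02)
  expect_silent(mwablate:::validate_surface(s$vertices, s$faces))
  lump <- ellipsoid_surface(c(0.01, 0.012, 0.02), subdiv = 2,
                            lumpy_amplitude = 0.05, seed = 4)
  expect_silent(mwablate:::validate_surface(lump$vertices, lump$faces))
  expect_false(isTRUE(all.equal(lump$volume, s$volume)))
})

test_that("surface import round-trips STL and reads OFF/PLY", {
  s <- ellipsoid_surface(c(0.008, 0.009, 0.012), center = c(0, 0, 0.01), subdiv = 2)
  fa <- tempfile(fileext = ".stl"); write_surface_stl(s, fa)
  ra <- load_tumor_surface(fa)
  expect_equal(ra$volume, s$volume, tolerance = 1e-9)
  fb <- tempfile(fileext = ".stl"); write_surface_stl(s, fb, binary = TRUE)
  rb <- load_tumor_surface(fb)
  expect_equal(rb$volume, s$volume, tolerance = 1e-6)

  # OFF and PLY readers on a tetrahedron written inline
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 1e-2
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  fo <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 4 6",
               apply(v, 1, paste, collapse = " "),
               apply(f - 1, 1, function(x) paste(c(3, x), collapse = " "))), fo)
  ro <- load_tumor_surface(fo)
  expect_equal(ro$volume, 1e-6 / 6, tolerance = 1e-9)
  fp <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header",
               apply(v, 1, paste, collapse = " "),
               apply(f - 1, 1, function(x) paste(c(3, x), collapse = " "))), fp)
  rp <- load_tumor_surface(fp)
  expect_equal(rp$volume, 1e-6 / 6, tolerance = 1e-9)
})

test_that("open, empty or malformed surfaces are rejected", {
  s <- ellipsoid_surface(c(0.01, 0.01, 0.01), subdiv = 1)
  open_s <- s; open_s$faces <- s$faces[-1, ]
  fo <- tempfile(fileext = ".stl"); write_surface_stl(open_s, fo)
  expect_error(load_tumor_surface(fo), "not closed")
  fe <- tempfile(fileext = ".stl"); file.create(fe)
  expect_error(load_tumor_surface(fe), "empty")
  expect_error(load_tumor_surface(tempfile(fileext = ".stl")), "cannot read")
  fx <- tempfile(fileext = ".xyz"); writeLines("junk", fx)
  expect_error(load_tumor_surface(fx), "unsupported")
})

test_that("generated meshes are fully tagged with consistent boundaries", {
  msh <- default_antenna_mesh()
  expect_true(all(msh$region %in% c("healthy_liver", "tumor", "catheter",
                                    "slot_fill", "antenna_dielectric",
                                    "antenna_metal")))
  expect_true(all(msh$nodes[, 1] >= 0))
  # region areas partition the rectangle exactly
  rect <- diff(range(msh$nodes[, 1])) * diff(range(msh$nodes[, 2]))
  expect_equal(sum(msh$area), rect, tolerance = 1e-12)
  # axis edges at r = 0; port edges on the coax cross-section
  ax <- msh$edges[msh$edge_tag == "axis", ]
  expect_true(all(abs(msh$nodes[as.vector(ax), 1]) < 1e-12))
  pt <- msh$edges[msh$edge_tag == "port", ]
  a <- msh$antenna$inner_conductor_radius
  b <- msh$antenna$dielectric_outer_radius
  expect_true(all(msh$nodes[as.vector(pt), 1] >= a - 1e-12 &
                  msh$nodes[as.vector(pt), 1] <= b + 1e-12))
  expect_true(all(abs(msh$nodes[as.vector(pt), 2] -
                      msh$antenna$insertion_depth) < 1e-12))
})

test_that("meshed tumor volume reproduces the analytic revolved ellipsoid within 1%", {
  msh <- default_antenna_mesh()
  tum <- msh$tumor
  vol <- region_volumes(msh)["tumor"]
  expect_lt(abs(vol / tum$volume - 1), 0.01)
})

test_that("mesh refinement grows the element count without inversion", {
  ant <- build_antenna()
  tum <- make_ellipsoid_tumor(c(0.8, 0.8, 1.5) * 1e-2)
  m1 <- generate_mesh(ant, tum, h_fine = 1.2e-3, h_coarse = 6e-3)
  m2 <- generate_mesh(ant, tum, h_fine = 0.6e-3, h_coarse = 6e-3)
  expect_gt(nrow(m2$tri), nrow(m1$tri))
  expect_true(all(m1$area > 0) && all(m2$area > 0))  # precompute rejects inversions
})

test_that("degenerate tumor placements are rejected", {
  ant <- build_antenna()
  too_big <- make_ellipsoid_tumor(c(0.06, 0.06, 0.06))
  expect_error(generate_mesh(ant, too_big), "does not fit")
  off_axis <- make_ellipsoid_tumor(c(0.008, 0.008, 0.01), center = c(0.01, 0, 0.01))
  expect_error(generate_mesh(ant, off_axis), "axis")
  # tumor entirely inside the antenna bore leaves no tumor elements
  inside <- make_ellipsoid_tumor(c(2e-4, 2e-4, 5e-4), center = c(0, 0, 0.03))
  expect_error(generate_mesh(ant, inside), "empty|bore")
})
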