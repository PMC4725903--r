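test_that("contour radius follows the clover-leaf polar form", {
  sh <- protein_shape(5, R = 1, eps = 0)
  expect_equal(contour_radius(sh, c(0, 1, 2.5)), rep(1, 3))
  sh2 <- protein_shape(5, R = 1, eps = 0.2, omega = 0)
  expect_equal(contour_radius(sh2, 0), 1.2)
  expect_equal(contour_radius(sh2, pi / 5), 0.8)
  expect_error(protein_shape(5, 1, eps = 1), "invalid shape")
  expect_error(protein_shape(3, 1), "symmetry order")
})

test_that("enclosed area matches direct quadrature of the contour", {
  for (pars in list(c(5, 2.27, 0.22), c(4, 2.27, 0.22), c(0, 2.3, 0))) {
    sh <- protein_shape(pars[1], pars[2], pars[3])
    quad <- integrate(function(th) 0.5 * contour_radius(sh, th)^2,
                      0, 2 * pi, rel.tol = 1e-12)$value
    expect_equal(shape_area(sh), quad, tolerance = 1e-10)
  }
})

test_that("contour is periodic in the symmetry sector and rotationally covariant", {
  sh <- protein_shape(5, 2.27, 0.22, omega = 0.4)
  th <- seq(0, 2 * pi, length.out = 57)
  expect_equal(contour_radius(sh, th), contour_radius(sh, th + 2 * pi / 5),
               tolerance = 1e-14)
  delta <- 0.31
  sh_rot <- protein_shape(5, 2.27, 0.22, omega = 0.4 + delta)
  expect_equal(contour_radius(sh, th), contour_radius(sh_rot, th + delta),
               tolerance = 1e-13)
})

test_that("area matching is s-independent and involution-consistent", {
  pent <- mscl_shape("pentamer", "closed")
  # equal eps: radius unchanged under 5 -> 4
  expect_equal(matched_area_radius(pent, 4L, pent$eps), pent$R, tolerance = 1e-12)
  # eps = 0 target reduces to the equal-area circle
  expect_equal(matched_area_radius(pent, 0L, 0), sqrt(shape_area(pent) / pi),
               tolerance = 1e-12)
  # pentamer -> tetramer (different eps) -> pentamer round trip
  R4 <- matched_area_radius(pent, 4L, 0.13)
  tet <- protein_shape(4, R4, 0.13)
  expect_equal(matched_area_radius(tet, 5L, pent$eps), pent$R, tolerance = 1e-8)
})

test_that("boundary conditions carry the signed hydrophobic half-mismatch", {
  b <- bilayer_params()
  closed <- mscl_shape("pentamer", "closed", b)
  open <- mscl_shape("pentamer", "open", b)
  expect_gt(boundary_conditions(closed, b)$u, 0)  # closed MscL thicker than bilayer
  expect_lt(boundary_conditions(open, b)$u, 0)
  expect_true(boundary_conditions(closed, b)$zero_slope)
  # linearity of the definition: doubling the mismatch doubles U
  sh <- protein_shape(5, 2, 0.2, U = 0.17)
  sh2 <- protein_shape(5, 2, 0.2, U = 0.34)
  expect_equal(boundary_conditions(sh2, b)$u, 2 * boundary_conditions(sh, b)$u)
  # matched thickness gives U = 0
  thickness <- 2 * b$a
  expect_equal(thickness / 2 - b$a, 0)
})

test_that("gating expands the footprint for every oligomer model", {
  for (olig in c("pentamer", "tetramer", "cylinder")) {
    expect_lt(mscl_shape(olig, "closed")$R, mscl_shape(olig, "open")$R)
  }
  # tetramer and pentamer cross sections agree state by state
  for (st in c("closed", "open")) {
    expect_equal(shape_area(mscl_shape("tetramer", st)),
                 shape_area(mscl_shape("pentamer", st)), tolerance = 1e-10)
  }
})

test_that("shapes serialize to flat lists and round-trip exactly", {
  sh <- protein_shape(4, 2.31, 0.17, omega = 0.21, U = -0.35, state = "open")
  rt <- shape_from_list(shape_to_list(sh))
  expect_identical(sh, rt)
  js <- jsonlite::fromJSON(jsonlite::toJSON(shape_to_list(sh), auto_unbox = TRUE,
                                            digits = NA))
  expect_identical(shape_from_list(js), sh)
})
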