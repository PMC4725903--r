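coarse_mesh <- function(shape, h_frac = 40, ...) {
  per <- msclattice:::contour_perimeter(shape)
  cfg <- particle_config(list(shape), rbind(c(0, 0)))
  mesh_patch(cfg, "disc", h_near = per / h_frac, h_far = 4 * per / h_frac,
             maxit = 15L, ...)
}

test_that("annulus mesh conserves area and has valid elements", {
  cyl <- mscl_shape("cylinder", "closed")
  m <- coarse_mesh(cyl, h_frac = 60)
  expect_true(all(m$areas > 0))
  Rout <- max(sqrt(rowSums(m$nodes^2)))
  expect_equal(mesh_area(m), pi * (Rout^2 - cyl$R^2), tolerance = 0.01)
  # contour nodes sit on the contour, outer nodes on the disc
  prot <- m$tags$protein[[1]]
  expect_gt(length(prot), 39)
  expect_lt(max(abs(sqrt(rowSums(m$nodes[prot, ]^2)) - cyl$R)), 1e-5)
  expect_gt(length(m$tags$outer), 15)
})

test_that("halving h roughly quadruples the element count", {
  tet <- mscl_shape("tetramer", "closed")
  # start from h_frac = 60: at 30 the far field is already at the minimum
  # resolution needed to tile the annulus, which masks the h^-2 scaling
  m1 <- coarse_mesh(tet, h_frac = 60)
  m2 <- coarse_mesh(tet, h_frac = 120)
  ratio <- nrow(m2$triangles) / nrow(m1$triangles)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
})

test_that("two proteins at contact mesh without inverted triangles", {
  tet <- mscl_shape("tetramer", "closed")
  dmin <- min_distance(tet, tet, pi / 4, pi / 4)
  cfg <- msclattice:::pair_config(tet, tet, dmin, pi / 4, pi / 4)
  per <- msclattice:::contour_perimeter(tet)
  m <- mesh_patch(cfg, "disc", h_near = per / 48, h_far = 4 * per / 48,
                  maxit = 15L)
  expect_true(all(m$areas > 1e-12))
  expect_equal(length(m$tags$protein), 2L)
  # overlapping contours are refused
  cfg_bad <- msclattice:::pair_config(tet, tet, 3.0, pi / 4, pi / 4)
  expect_error(mesh_patch(cfg_bad, "disc", h_near = per / 40,
                          h_far = per / 10), "overlap")
})

test_that("solved energy is invariant under node relabeling", {
  cyl <- mscl_shape("cylinder", "closed")
  m <- coarse_mesh(cyl, h_frac = 40)
  p <- bilayer_params()
  E1 <- solve_field(m, p)$E_excess
  set.seed(7)
  perm <- sample(nrow(m$nodes))
  inv <- order(perm)
  m2 <- m
  m2$nodes <- m$nodes[perm, ]
  m2$triangles <- matrix(inv[m$triangles], ncol = 3)
  m2$tags$protein <- lapply(m$tags$protein, function(i) inv[i])
  m2$tags$outer <- inv[m$tags$outer]
  E2 <- solve_field(m2, p)$E_excess
  expect_equal(E1, E2, tolerance = 1e-12)
})

test_that("far-field truncation is converged at the default margin", {
  cyl <- mscl_shape("cylinder", "closed")
  p <- bilayer_params()
  per <- msclattice:::contour_perimeter(cyl)
  cfg <- particle_config(list(cyl), rbind(c(0, 0)))
  lam <- decay_length(p)
  m1 <- mesh_patch(cfg, "disc", outer_size = cyl$R + 10 * lam,
                   h_near = per / 48, h_far = 4 * per / 48, maxit = 15L)
  m2 <- mesh_patch(cfg, "disc", outer_size = cyl$R + 20 * lam,
                   h_near = per / 48, h_far = 4 * per / 48, maxit = 15L)
  E1 <- solve_field(m1, p)$E_excess
  E2 <- solve_field(m2, p)$E_excess
  expect_lt(abs(E1 - E2) / abs(E1), 1e-3)
})

test_that("symmetry cells report the right protein fraction and tags", {
  cyl <- mscl_shape("cylinder", "closed")
  sq <- build_symmetry_cell(lattice_spec("square", d = 6.5,
                                         orientation = "horizontal"), cyl,
                            h_frac = 48, maxit = 15L)
  expect_equal(sq$f, 1)
  expect_gt(length(sq$mesh$tags$sym_x), 0)
  expect_gt(length(sq$mesh$tags$sym_y), 0)
  hx <- build_symmetry_cell(lattice_spec("hexagonal", d = 6.5,
                                         orientation = "horizontal"), cyl,
                            h_frac = 48, maxit = 15L)
  expect_equal(hx$f, 2)
  hc <- build_symmetry_cell(lattice_spec("honeycomb", d = 6.5,
                                         orientation = "horizontal"), cyl,
                            h_frac = 48, maxit = 15L)
  expect_equal(hc$f, 4)
})

test_that("orientation schemes breaking the cell mirrors are refused", {
  pent <- mscl_shape("pentamer", "closed")
  expect_error(
    build_symmetry_cell(lattice_spec("square", d = 7, orientation = "face-on"),
                        pent, h_frac = 40),
    "symmetry-violation")
})

test_that("cell energy per protein approaches the isolated energy at large d", {
  cyl <- mscl_shape("cylinder", "closed")
  p <- bilayer_params()
  e_int <- lattice_energy_infinite(lattice_spec("square", d = 13.5,
                                                orientation = "horizontal"),
                                   cyl, p, h_frac = 56, maxit = 15L)
  E1 <- msclattice:::single_protein_energy(cyl, p, 56, NULL, 15L)
  expect_lt(abs(e_int) / E1, 0.01)
})
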