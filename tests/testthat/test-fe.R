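# triangle used by the element patch tests
tri <- rbind(c(0, 0), c(1.3, 0.2), c(0.4, 1.1))
tri_area <- 0.5 * abs((tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
                      (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2]))
dofs_of <- function(u, ux, uy) as.vector(t(cbind(u, ux, uy)))

test_that("element reproduces constant-curvature, stretch and tension energies", {
  pc <- bilayer_params(kappa_b = 2.5, K_t = 1e-9, a = 1, tau = 0)
  K <- element_matrices(tri, pc)$K
  expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
  # u = x^2/2 and y^2/2: lap u = 1, energy kb/2 * A
  d <- dofs_of(tri[, 1]^2 / 2, tri[, 1], 0)
  expect_equal(0.5 * drop(t(d) %*% K %*% d), 2.5 / 2 * tri_area, tolerance = 1e-10)
  d <- dofs_of(tri[, 2]^2 / 2, 0, tri[, 2])
  expect_equal(0.5 * drop(t(d) %*% K %*% d), 2.5 / 2 * tri_area, tolerance = 1e-10)
  # harmonic twist u = xy and rigid translation carry no curvature energy
  d <- dofs_of(tri[, 1] * tri[, 2], tri[, 2], tri[, 1])
  expect_lt(0.5 * drop(t(d) %*% K %*% d), 1e-8)
  d <- dofs_of(rep(1, 3), 0, 0)
  # bound must sit above the deliberate K_t = 1e-9 placeholder contribution
  expect_lt(0.5 * drop(t(d) %*% K %*% d), 1e-8)
  # stretch: u = c costs Kt/(2 a^2) c^2 A
  ps <- bilayer_params(kappa_b = 1e-9, K_t = 60, a = 1.6, tau = 0)
  Ks <- element_matrices(tri, ps)$K
  d <- dofs_of(rep(0.7, 3), 0, 0)
  expect_equal(0.5 * drop(t(d) %*% Ks %*% d),
               60 / (2 * 1.6^2) * 0.49 * tri_area, tolerance = 1e-10)
  # tension gradient: linear slope (3, -1) costs tau/2 |grad|^2 A
  pt <- bilayer_params(kappa_b = 1e-9, K_t = 1e-9, a = 1.6, tau = 2)
  Kt_ <- element_matrices(tri, pt)$K
  d <- dofs_of(2 + 3 * tri[, 1] - tri[, 2], 3, -1)
  expect_equal(0.5 * drop(t(d) %*% Kt_ %*% d), 2 / 2 * 10 * tri_area,
               tolerance = 1e-9)
  # internal-tension load: f = (tau/a) * A/3 on the u DOFs
  f <- element_matrices(tri, pt)$f
  expect_equal(f[c(1, 4, 7)], rep(2 / 1.6 * tri_area / 3, 3), tolerance = 1e-12)
  expect_equal(f[c(2, 3, 5, 6, 8, 9)], rep(0, 6))
  expect_error(element_matrices(tri[c(1, 1, 2), ], pc), "singular-element")
})

cyl_mesh <- function(h_frac = 64, params = bilayer_params(), maxit = 15L) {
  cyl <- mscl_shape("cylinder", "closed")
  per <- msclattice:::contour_perimeter(cyl)
  cfg <- particle_config(list(cyl), rbind(c(0, 0)))
  mesh_patch(cfg, "disc", h_near = per / h_frac, h_far = 4 * per / h_frac,
             params = params, maxit = maxit)
}

test_that("zero mismatch gives the flat membrane and energies scale quadratically", {
  p <- bilayer_params()
  m <- cyl_mesh(40)
  f0 <- solve_field(m, p, bcs = 0)
  expect_lt(abs(f0$E_excess), 1e-10)
  expect_lt(max(abs(f0$u)), 1e-10)
  fU <- solve_field(m, p)
  for (c in c(2, -1.7)) {
    fc <- solve_field(m, p, bcs = c * mscl_shape("cylinder", "closed")$U)
    expect_equal(fc$E_excess / fU$E_excess, c^2, tolerance = 1e-8)
  }
})

test_that("assembled quadratic form agrees with direct quadrature of the field", {
  p <- bilayer_params(tau = 0.8)
  m <- cyl_mesh(48, params = p)
  f <- solve_field(m, p)
  q <- energy_quadrature(f)
  expect_equal(q$total, f$E, tolerance = 1e-6)
})

test_that("direct sparse solve and L-BFGS-B minimization agree", {
  p <- bilayer_params()
  m <- cyl_mesh(32)
  e1 <- solve_field(m, p, method = "cholesky")$E_excess
  e2 <- solve_field(m, p, method = "lbfgs")$E_excess
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("energy is invariant under rigid rotation of the whole problem", {
  p <- bilayer_params()
  tet <- mscl_shape("tetramer", "closed")
  per <- msclattice:::contour_perimeter(tet)
  cfg <- particle_config(list(tet), rbind(c(0, 0)))
  m <- mesh_patch(cfg, "disc", h_near = per / 48, h_far = 4 * per / 48,
                  maxit = 15L)
  E1 <- solve_field(m, p)$E_excess
  a <- 0.7321
  Rm <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  m2 <- m
  m2$nodes <- m$nodes %*% t(Rm)
  E2 <- solve_field(m2, p)$E_excess
  expect_lt(abs(E1 - E2) / abs(E1), 1e-4)
})

test_that("analytic cylinder profile satisfies its boundary value problem", {
  for (tau in c(0, 1.2)) {
    p <- bilayer_params(tau = tau)
    cyl <- mscl_shape("cylinder", "closed")
    an <- analytic_cylinder(p, cyl$R, cyl$U)
    expect_equal(an$profile(cyl$R), cyl$U, tolerance = 1e-8)
    h <- 1e-6
    expect_lt(abs((an$profile(cyl$R + h) - an$profile(cyl$R)) / h), 1e-4)
    # decay to the tension-set far-field thickness
    expect_equal(an$profile(20), an$u0, tolerance = 1e-5)
    expect_equal(an$u0, if (tau > 0) -p$a * tau / p$K_t else 0)
    # quadratic scaling of the boundary-flux energy
    an2 <- analytic_cylinder(p, cyl$R, an$u0 + 2 * (cyl$U - an$u0))
    expect_equal(an2$energy / an$energy, 4, tolerance = 1e-10)
  }
})

test_that("boundary-flux energy equals 1D quadrature of the energy density", {
  p <- bilayer_params()
  an <- analytic_cylinder(p, 2.3, 0.3)
  v <- an$profile
  h <- 1e-4
  dens <- function(r) vapply(r, function(rr) {
    lap <- (v(rr + h) - 2 * v(rr) + v(rr - h)) / h^2 +
      (v(rr + h) - v(rr - h)) / (2 * h) / rr
    (p$kappa_b / 2 * lap^2 + p$K_t / (2 * p$a^2) * v(rr)^2) * 2 * pi * rr
  }, 0)
  Eq <- integrate(dens, 2.3, 16, rel.tol = 1e-8)$value
  expect_equal(an$energy, Eq, tolerance = 1e-5)
  expect_error(analytic_cylinder(p, -1, 0.3), "positive")
})

test_that("FE energy matches the analytic oracle within 1 percent", {
  for (tau in c(0, 1.0)) {
    p <- bilayer_params(tau = tau)
    cyl <- mscl_shape("cylinder", "closed")
    m <- cyl_mesh(96, params = p, maxit = 20L)
    fe <- solve_field(m, p)
    an <- analytic_cylinder(p, cyl$R, cyl$U)
    expect_lt(abs(fe$E_excess - an$energy) / abs(an$energy), 0.01)
  }
  # open state too
  p <- bilayer_params()
  op <- mscl_shape("cylinder", "open")
  per <- msclattice:::contour_perimeter(op)
  cfg <- particle_config(list(op), rbind(c(0, 0)))
  m <- mesh_patch(cfg, "disc", h_near = per / 96, h_far = 4 * per / 96,
                  maxit = 20L)
  fe <- solve_field(m, p)
  an <- analytic_cylinder(p, op$R, op$U)
  expect_lt(abs(fe$E_excess - an$energy) / abs(an$energy), 0.01)
})

test_that("gradient validity check flags elements against the threshold", {
  p <- bilayer_params()
  m <- cyl_mesh(40)
  f0 <- solve_field(m, p, bcs = 0)
  g0 <- gradient_validity_check(f0)
  expect_equal(g0$max_grad, 0, tolerance = 1e-10)
  f <- solve_field(m, p)
  g <- gradient_validity_check(f)
  expect_gt(g$max_grad, 0)
  expect_lt(g$max_grad, 0.5) # leading-order model valid for closed MscL
  gz <- gradient_validity_check(f, threshold = 0)
  expect_gt(gz$frac_exceed, 0.5) # all deformed elements flagged
})
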