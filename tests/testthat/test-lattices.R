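test_that("lattice builders produce the right counts and coordination", {
  tet <- mscl_shape("tetramer", "closed")
  sq <- build_lattice(lattice_spec("square", d = 6, orientation = "face-on",
                                   L = 3), tet)
  expect_equal(n_proteins(sq), 9L)
  # center protein has 4 neighbours at spacing d
  dmat <- as.matrix(dist(sq$pos))
  center <- which.min(rowSums(sweep(sq$pos, 2, colMeans(sq$pos))^2))
  expect_equal(sum(abs(dmat[center, ] - 6) < 1e-9), 4L)
  hx <- build_lattice(lattice_spec("hexagonal", d = 6.5,
                                   orientation = "horizontal", L = 4),
                      mscl_shape("cylinder", "closed"))
  dm <- as.matrix(dist(hx$pos))
  ch <- which.min(rowSums(sweep(hx$pos, 2, colMeans(hx$pos))^2))
  expect_equal(sum(abs(dm[ch, ] - 6.5) < 1e-6), 6L)
  hc <- build_lattice(lattice_spec("honeycomb", d = 6.5,
                                   orientation = "horizontal", N = 32),
                      mscl_shape("cylinder", "closed"))
  expect_equal(n_proteins(hc), 32L)
  # steric guard
  expect_error(build_lattice(lattice_spec("square", d = 4,
                                          orientation = "face-on", L = 2), tet),
               "packing error")
})

test_that("degenerate and non-interacting lattices have zero energy", {
  tb <- fx_tab_tet()
  tet <- mscl_shape("tetramer", "closed")
  expect_equal(lattice_energy_finite(
    lattice_spec("square", d = 6, orientation = "face-on", L = 1),
    tet, table = tb), 0)
  expect_equal(lattice_energy_finite(
    lattice_spec("square", d = tb$d_cut + 0.5, orientation = "face-on", L = 3),
    tet, table = tb), 0)
})

test_that("tetramer clusters order as face-on square < shifted < hexagonal", {
  tb <- fx_tab_tet()
  tet <- mscl_shape("tetramer", "closed")
  espec <- function(fam) {
    sp <- lattice_spec(fam, d = 6, orientation = "face-on", L = 4)
    sp$d <- lattice_min_spacing(sp, tet)
    lattice_energy_finite(sp, tet, table = tb)
  }
  e_sq <- espec("square"); e_sh <- espec("shifted-square"); e_hx <- espec("hexagonal")
  expect_lt(e_sq, e_sh)
  expect_lt(e_sh, e_hx)
})

test_that("finite pairwise energies converge toward the infinite lattice", {
  tb <- fx_tab_cyl()
  cyl <- mscl_shape("cylinder", "closed")
  sp <- lattice_spec("hexagonal", d = 6.3, orientation = "horizontal")
  e_inf <- infinite_pairwise_energy(sp, cyl, tb)
  gaps <- vapply(c(3L, 5L, 8L), function(L) {
    s2 <- sp; s2$L <- L
    abs(lattice_energy_finite(s2, cyl, table = tb) - e_inf)
  }, 0)
  expect_true(all(diff(gaps) < 0))
})

test_that("symmetry-cell and pairwise infinite energies agree for cylinders", {
  tb <- fx_tab_cyl()
  cyl <- mscl_shape("cylinder", "closed")
  p <- bilayer_params()
  sp <- lattice_spec("square", d = 6.5, orientation = "horizontal")
  e_cell <- lattice_energy_infinite(sp, cyl, p, h_frac = 64, maxit = 20L)
  e_pair <- infinite_pairwise_energy(sp, cyl, tb)
  # multi-body corrections and table coarseness both enter; agreement is
  # structural, not exact
  expect_lt(abs(e_cell - e_pair), 0.25 * abs(e_cell) + 0.3)
})

test_that("candidate ranking is independent of evaluation order", {
  tb <- fx_tab_cyl()
  cyl <- mscl_shape("cylinder", "closed")
  dmin <- min_distance(cyl, cyl)
  ds <- seq(dmin + 0.01, 10, length.out = 5)
  specs <- list(lattice_spec("hexagonal", d = 1, orientation = "horizontal"),
                lattice_spec("square", d = 1, orientation = "horizontal"),
                lattice_spec("honeycomb", d = 1, orientation = "horizontal"))
  r1 <- ground_state_scan(cyl, specs, list(ds, ds, ds), table = tb)
  r2 <- ground_state_scan(cyl, rev(specs), list(ds, ds, ds), table = tb)
  expect_equal(r1$ranking$family, r2$ranking$family)
  expect_equal(r1$ranking$energy_min, r2$ranking$energy_min, tolerance = 1e-12)
  expect_equal(r1$ranking$family[1], "hexagonal")
})

test_that("boundary effects decay with cluster size toward the bulk difference", {
  tb <- fx_tab_tet()
  tet <- mscl_shape("tetramer", "closed")
  sq <- lattice_spec("square", d = 6, orientation = "face-on")
  sq$d <- lattice_min_spacing(sq, tet)
  sh <- lattice_spec("shifted-square", d = sq$d, orientation = "face-on")
  same <- boundary_scaling(sq, sq, tet, tb, L_range = c(3L, 4L, 5L))
  expect_true(all(abs(same$data$dE) < 1e-12))
  bs <- boundary_scaling(sq, sh, tet, tb, L_range = 3:6)
  # face-on square is favored over shifted square in finite clusters and the
  # difference shrinks toward the near-degenerate bulk limit
  expect_true(all(bs$data$dE < 0))
  expect_true(abs(bs$data$dE[4] - bs$dE_inf) < abs(bs$data$dE[1] - bs$dE_inf))
  bs2 <- boundary_scaling(sq, sh, tet, tb, L_range = 4:7)
  expect_lt(abs(bs2$exponent - bs$exponent), 0.2 * abs(bs$exponent) + 0.15)
})

test_that("densest alternating-row packing is steric-contact limited", {
  mp <- fx_max_packing_pent()
  pent <- mscl_shape("pentamer", "closed")
  cl <- mscl_defaults()$steric$edge_clearance
  cfg <- build_lattice(mp$spec, pent, check_steric = FALSE)
  np <- msclattice:::neighbor_pairs(cfg, r_cut = 8)
  gaps <- vapply(seq_len(nrow(np)), function(r)
    contour_gap(cfg$shapes[[np[r, 1]]], cfg$pos[np[r, 1], ],
                cfg$shapes[[np[r, 2]]], cfg$pos[np[r, 2], ]), 0)
  expect_true(all(gaps > cl - 0.02))       # no steric violation
  expect_lt(min(gaps), cl + 0.05)          # at least one pair at contact
  # alternating rows pack denser than the uniform-orientation hexagonal
  hx <- lattice_spec("hexagonal", d = 1, orientation = "horizontal")
  d_hx <- lattice_min_spacing(hx, pent)
  phi_hx <- shape_area(pent) / (sqrt(3) / 2 * d_hx^2)
  expect_gt(mp$phi, phi_hx)
})
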