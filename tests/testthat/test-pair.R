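test_that("steric minimum distances follow the contour geometry", {
  cyl <- mscl_shape("cylinder", "closed")
  cl <- mscl_defaults()$steric$edge_clearance
  expect_equal(min_distance(cyl, cyl), 2 * cyl$R + cl, tolerance = 1e-3)
  tet <- mscl_shape("tetramer", "closed")
  d_tip <- min_distance(tet, tet, 0, 0)
  d_face <- min_distance(tet, tet, pi / 4, pi / 4)
  expect_gt(d_tip, d_face)
  # swap symmetry: viewing the pair from B's side flips the axis, so both
  # orientations pick up a pi shift (a no-op for even s only)
  pent <- mscl_shape("pentamer", "closed")
  expect_equal(min_distance(tet, pent, 0.3, 0.8),
               min_distance(pent, tet, 0.8 + pi, 0.3 + pi), tolerance = 1e-3)
})

test_that("pair energy is periodic in each symmetry sector", {
  tb <- fx_tab_tet()
  d <- tb$d_grid[6]
  expect_equal(pair_lookup(tb, d, 0.3, 0.7),
               pair_lookup(tb, d, 0.3 + pi / 2, 0.7))
  expect_equal(pair_lookup(tb, d, 0.3, 0.7),
               pair_lookup(tb, d, 0.3, 0.7 + pi))
})

test_that("lookup reproduces grid points, interpolates linearly, cuts off", {
  tb <- fx_tab_tet()
  i <- 2L; j <- 3L; k <- 8L
  expect_identical(pair_lookup(tb, tb$d_grid[k], tb$w1_grid[i], tb$w2_grid[j]),
                   tb$E[k, i, j])
  mid <- (tb$d_grid[k] + tb$d_grid[k + 1]) / 2
  expect_equal(pair_lookup(tb, mid, tb$w1_grid[i], tb$w2_grid[j]),
               (tb$E[k, i, j] + tb$E[k + 1, i, j]) / 2, tolerance = 1e-12)
  expect_identical(pair_lookup(tb, tb$d_cut + 1), 0)
  expect_error(pair_lookup(tb, 3.0, 0, 0), "overlap")
})

test_that("closed-closed potential is attractive at contact, repulsive midrange", {
  for (tb in list(fx_tab_tet(), fx_tab_pent())) {
    nw1 <- length(tb$w1_grid); nw2 <- length(tb$w2_grid)
    contact <- vapply(seq_len(nw1), function(i) {
      vapply(seq_len(nw2), function(j) {
        v0 <- which(!is.na(tb$E[, i, j]))[1]
        tb$E[v0, i, j]
      }, 0)
    }, numeric(nw2))
    expect_true(all(contact < 0))          # strongly favorable at contact
    # rows entirely below dmin are all-NA and reduce to -Inf; harmless here
    mid <- suppressWarnings(apply(tb$E, 1, max, na.rm = TRUE))
    expect_gt(max(mid), 0.1)               # weakly unfavorable barrier
  }
})

test_that("orientation-averaged envelope decays beyond the barrier", {
  tb <- fx_tab_tet()
  env <- suppressWarnings(apply(abs(tb$E), 1, max, na.rm = TRUE))
  ipk <- which.max(suppressWarnings(apply(tb$E, 1, max, na.rm = TRUE)))
  tail <- env[ipk:length(env)]
  # allow small mesh-noise wiggles but demand overall decay
  expect_lt(tail[length(tail)], 0.15)
  expect_gt(tail[1], 3 * tail[length(tail)])
})

test_that("site-exchange symmetry holds on the tabulated grid", {
  tb <- fx_tab_tet()  # s = 4: pi shift is 0 mod sector, so E(d,w1,w2) = E(d,w2,w1)
  nw <- length(tb$w1_grid)
  for (i in seq_len(nw)) for (j in seq_len(nw)) {
    expect_equal(tb$E[, i, j], tb$E[, j, i], tolerance = 1e-12)
  }
})

test_that("cylinder tables are orientation-independent by construction", {
  tb <- fx_tab_cyl()
  expect_identical(dim(tb$E)[2:3], c(1L, 1L))
  expect_equal(pair_lookup(tb, 7, 1.3, 2.1), pair_lookup(tb, 7, 0, 0))
})

test_that("pair energies vanish at the cutoff at converged resolution", {
  tails <- fx_tail_energies()
  expect_lt(abs(tails[["tet_tip"]]), 0.05)
  expect_lt(abs(tails[["tet_face"]]), 0.05)
})

test_that("global rotation covariance: energy depends on bond-relative angles", {
  tb <- fx_tab_tet()
  # rotating both proteins and the bond together leaves the lookup unchanged
  d <- tb$d_grid[5]
  for (rot in c(0.4, 1.2)) {
    e0 <- pair_lookup(tb, d, 0.5, 1.0)
    # orientations and bond rotated by `rot`: relative angles unchanged
    w1 <- 0.5 + rot - rot; w2 <- 1.0 + rot - rot
    expect_equal(pair_lookup(tb, d, w1, w2), e0)
  }
})

test_that("two-body configurations have zero non-pairwise deviation", {
  cyl <- mscl_shape("cylinder", "closed")
  cfg <- msclattice:::pair_config(cyl, cyl, 7, 0, 0)
  dev <- nonpairwise_deviation(cfg, h_frac = 48, margin_lambda = 6, maxit = 12L)
  expect_lt(abs(dev$deviation), 0.15)  # FE tolerance only
})

test_that("well-separated proteins have vanishing multi-body corrections", {
  cyl <- mscl_shape("cylinder", "closed")
  dcut <- fx_tab_cyl()$d_cut
  pos <- rbind(c(0, 0), c(dcut + 1, 0), c((dcut + 1) / 2, dcut + 1))
  cfg <- particle_config(rep(list(cyl), 3), pos)
  dev <- nonpairwise_deviation(cfg, table = fx_tab_cyl(), h_frac = 48,
                               margin_lambda = 6, maxit = 12L)
  expect_lt(abs(dev$deviation) / 3, 0.1)
})

test_that("near-contact trimer shows a nonzero multi-body correction", {
  cyl <- mscl_shape("cylinder", "closed")
  d <- min_distance(cyl, cyl) + 0.05
  pos <- d * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  cfg <- particle_config(rep(list(cyl), 3), pos)
  dev <- nonpairwise_deviation(cfg, h_frac = 64, margin_lambda = 6, maxit = 12L)
  # regression window: multi-body corrections are a modest fraction of the
  # pair sum at contact
  expect_lt(abs(dev$deviation), 0.35 * abs(dev$pair_sum))
  expect_gt(abs(dev$deviation), 0.02)
})

test_that("pair tables round-trip through CSV + JSON sidecar", {
  tb <- fx_tab_tet()
  pre <- file.path(tempdir(), "tab_rt")
  write_pair_table(tb, pre)
  tb2 <- read_pair_table(pre)
  expect_equal(tb2$E, tb$E)
  expect_equal(tb2$dmin, tb$dmin)
  expect_equal(tb2$d_grid, tb$d_grid)
  expect_identical(tb2$shapeA$label, tb$shapeA$label)
  expect_equal(pair_lookup(tb2, 7.1, 0.2, 0.9), pair_lookup(tb, 7.1, 0.2, 0.9))
})
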